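#' Boynton gamma hemodynamic response function
#'
#' The canonical gamma-variate impulse response
#' \deqn{h(t) = \frac{(t/\tau)^{n-1} e^{-t/\tau}}{\tau (n-1)!}, \quad t > 0}
#' sampled at the TR and normalized to unit sum, so that convolving a
#' sustained neural signal leaves its asymptotic amplitude unchanged.
#' The continuous-time response peaks at \eqn{t = (n-1)\tau} (2.4 s for
#' the defaults n = 3, tau = 1.2 s).
#'
#' @param trS sampling interval (TR), seconds
#' @param n gamma shape (default 3)
#' @param tauS gamma time constant, seconds (default 1.2)
#' @param delayS pure onset delay, seconds (default 0)
#' @param massTol kernel is truncated once the remaining (un-normalized)
#'   tail mass falls below this tolerance
#' @return numeric kernel starting at lag 0, with attribute
#'   \code{params}; \code{kernel[1]} corresponds to t = 0 and is 0
#'   (causality)
#' @examples
#' h <- boyntonHrf(2)
#' sum(h)  # 1
#' @export
boyntonHrf <- function(trS, n = 3, tauS = 1.2, delayS = 0, massTol = 1e-6) {
  if (trS <= 0 || tauS <= 0 || n < 1)
    stop("boyntonHrf: trS and tauS must be positive and n >= 1")
  if (delayS < 0) stop("boyntonHrf: delayS must be non-negative")
  g <- function(t) {
    ts <- t - delayS
    out <- numeric(length(t))
    pos <- ts > 0
    out[pos] <- (ts[pos] / tauS)^(n - 1) * exp(-ts[pos] / tauS) /
      (tauS * gamma(n))
    out
  }
  # extend until the un-normalized discrete tail is negligible
  len <- 8L
  repeat {
    tt <- (seq_len(len) - 1) * trS
    k <- g(tt) * trS
    if (k[len] < massTol && len * trS > delayS + n * tauS * 4) break
    len <- len * 2L
    if (len > 1e5) break
  }
  k <- k[seq_len(max(which(k >= massTol), 2L))]
  k <- k / sum(k)
  attr(k, "params") <- list(n = n, tauS = tauS, delayS = delayS, trS = trS)
  k
}

#' Causal discrete convolution truncated to the input length
#'
#' Direct (non-FFT) convolution, so zero stretches of the input stay
#' exactly zero in the output.
#'
#' @param x numeric signal
#' @param kernel impulse response starting at lag 0
#' @return numeric vector of \code{length(x)}
#' @export
convolveHrf <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (l in seq_along(kernel)) {
    if (kernel[l] == 0 || l > n) next
    out[l:n] <- out[l:n] + kernel[l] * x[seq_len(n - l + 1)]
  }
  out
}
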