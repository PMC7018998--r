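#' Brightness-mixture deconvolution of oligomer fractions
#'
#' Classifies mobile entities by brightness: the brightness of a k-mer is
#' the k-fold convolution of the monomer brightness distribution (k
#' independently labeled protomers). The mixture weights over k = 1..K are
#' fitted by maximum likelihood (EM over the weights; the component
#' densities are fixed k-fold numerical convolutions of the monomer
#' reference), with non-negativity and sum-to-one enforced by construction.
#'
#' @param brightness_values numeric sample of entity brightness values.
#' @param monomer_reference either a numeric sample of monomer brightness
#'   values (a kernel density estimate is used) or a list
#'   `list(meanlog=, sdlog=)` for a parametric lognormal reference.
#' @param K maximum oligomer size (default 4).
#' @param grid_n grid size for the numerical convolutions.
#' @param max_iter,tol EM stopping parameters.
#' @return object of class `toccsl_brightness_fit`: `weights` (length K,
#'   sums to 1), `loglik`, `n`, `K`.
#' @export
brightness_mixture_fit <- function(brightness_values, monomer_reference,
                                   K = 4, grid_n = 4096, max_iter = 500,
                                   tol = 1e-8) {
  x <- brightness_values[is.finite(brightness_values) & brightness_values > 0]
  if (length(x) < 10L) stop("brightness_mixture_fit: too few values")
  upper <- max(x) * 1.05
  grid <- seq(0, upper, length.out = grid_n)
  h <- grid[2L] - grid[1L]

  if (is.list(monomer_reference)) {
    f1 <- stats::dlnorm(grid, monomer_reference$meanlog,
                        monomer_reference$sdlog)
  } else {
    kd <- density(monomer_reference, from = 0, to = upper, n = grid_n)
    f1 <- pmax(0, approx(kd$x, kd$y, grid, rule = 2)$y)
  }
  f1 <- f1 / (sum(f1) * h)

  # k-fold convolutions on the grid (FFT, zero-padded to avoid wrap-around)
  comp <- matrix(0, grid_n, K)
  comp[, 1L] <- f1
  if (K > 1L) {
    pad <- 2L * grid_n
    F1 <- stats::fft(c(f1, rep(0, pad - grid_n)))
    Fk <- F1
    for (k in 2:K) {
      Fk <- Fk * F1 * h
      fk <- Re(stats::fft(Fk, inverse = TRUE)) / pad
      comp[, k] <- pmax(0, fk[seq_len(grid_n)])
      comp[, k] <- comp[, k] / (sum(comp[, k]) * h)
    }
  }
  # per-observation component densities by interpolation
  dens <- vapply(seq_len(K), function(k)
    pmax(1e-300, approx(grid, comp[, k], x, rule = 2)$y),
    numeric(length(x)))

  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    num <- sweep(dens, 2, w, "*")
    rowsum_ <- rowSums(num)
    ll <- sum(log(rowsum_))
    resp <- num / rowsum_
    w <- colMeans(resp)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  structure(list(weights = w, loglik = ll, n = length(x), K = K),
            class = "toccsl_brightness_fit")
}

#' @export
print.toccsl_brightness_fit <- function(x, ...) {
  cat("Brightness mixture weights (k = 1..", x$K, "):\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}
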