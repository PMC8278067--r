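#' Split-chain R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the diagnostic.
#'
#' @param x Iterations x chains matrix of draws for one parameter.
#' @return R-hat (>= 1; values above ~1.05 indicate non-convergence).
#' @export
split_rhat <- function(x) {
  m <- split_chain_halves(as.matrix(x))
  n <- nrow(m)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size (split chains, initial positive sequence)
#'
#' @param x Iterations x chains matrix of draws for one parameter.
#' @return Estimated effective number of independent draws.
#' @export
ess_basic <- function(x) {
  m <- split_chain_halves(as.matrix(x))
  n <- nrow(m); nc <- ncol(m)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(n * nc)
  lag_max <- min(n - 2L, 500L)
  acov <- sapply(seq_len(nc), function(c) {
    a <- stats::acf(m[, c], lag.max = lag_max, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(as.matrix(acov)[-1, , drop = FALSE])) / var_plus
  # Geyer initial positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair < 0) break
    s <- s + pair
  }
  ess <- nc * n / (1 + 2 * s)
  min(ess, nc * n)
}

split_chain_halves <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[seq.int(n - h + 1L, n), , drop = FALSE])
}

#' Summarize a 3-d draws array
#'
#' @param draws Array with dimensions (iterations, chains, parameters) and
#'   named parameters.
#' @return Data frame with posterior mean, sd, 2.5/97.5 percent quantiles,
#'   split R-hat and effective sample size per parameter.
#' @export
summarize_draws <- function(draws) {
  stopifnot(length(dim(draws)) == 3L)
  pars <- dimnames(draws)[[3]]
  out <- do.call(rbind, lapply(seq_along(pars), function(j) {
    m <- draws[, , j, drop = FALSE]
    dim(m) <- dim(draws)[1:2]
    v <- as.vector(m)
    data.frame(parameter = pars[j], mean = mean(v), sd = stats::sd(v),
               q2.5 = unname(stats::quantile(v, 0.025)),
               q97.5 = unname(stats::quantile(v, 0.975)),
               rhat = split_rhat(m), ess = ess_basic(m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
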