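#' Wiener first-passage time density
#'
#' Density of the decision time (observed RT minus non-decision time) at
#' which a unit-diffusion process with drift `v`, boundary separation `a`
#' and relative start point `z` (proportion of `a`; 0.5 = neutral) first
#' hits the requested boundary. In the response-coded task model the upper
#' boundary is a smile and the lower a frown. The implementation switches
#' adaptively between the small-time and large-time series expansions
#' (truncation for `eps` absolute tolerance) and satisfies the reflection
#' identity: the lower density at (v, z) equals the upper density at
#' (-v, 1 - z).
#'
#' @param t Decision times, strictly positive (seconds).
#' @param v Drift rate (evidence units per second, positive toward the
#'   upper/smile boundary).
#' @param a Boundary separation, > 0.
#' @param z Relative start point in (0, 1).
#' @param boundary `"upper"` or `"lower"`.
#' @param log Return log density.
#' @param eps Absolute series truncation tolerance.
#' @return Vector of (log) densities.
#' @examples
#' dwiener(1, v = 0, a = 2, z = 0.5, "upper")
#' @export
dwiener <- function(t, v, a, z, boundary = c("upper", "lower"), log = FALSE,
                    eps = 1e-7) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be positive and finite")
  if (!is.finite(v) || !is.finite(a) || a <= 0) stop("invalid drift/boundary")
  if (z <= 0 || z >= 1) stop("z must be in (0, 1)")
  dwiener_cpp(as.numeric(t), v, a, z, boundary == "upper", log, eps)
}

#' Probability of an upper-boundary response (closed form)
#'
#' For unit diffusion, `P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))`
#' for nonzero drift, and `z` when `v = 0`.
#'
#' @inheritParams dwiener
#' @return Probability in (0, 1).
#' @export
pwiener_upper <- function(v, a, z) {
  stopifnot(a > 0, z > 0, z < 1)
  if (abs(v) < 1e-12) return(z)
  expm1(-2 * v * a * z) / expm1(-2 * v * a)
}

#' Simulate Wiener first-passage observations
#'
#' Euler-Maruyama forward walk from `z * a` between absorbing boundaries 0
#' and `a`, drift `v`, unit diffusion; RT is the crossing time plus `t0`.
#' Walks that have not terminated after `horizon` seconds are excluded and
#' counted in the `"n_timeout"` attribute.
#'
#' @inheritParams dwiener
#' @param n Number of observations.
#' @param t0 Non-decision time added to the crossing time (seconds).
#' @param dt Euler step (seconds).
#' @param seed Optional integer seed.
#' @param horizon Maximum decision time before an observation is flagged.
#' @return Data frame with columns `rt` (seconds) and `boundary`
#'   (`"upper"`/`"lower"`), attribute `n_timeout`.
#' @export
rwiener <- function(n, v, a, z, t0 = 0, dt = 1e-4, seed = NULL, horizon = 20) {
  stopifnot(n >= 1, dt > 0, a > 0, z > 0, z < 1, t0 >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  sim <- rwiener_cpp(as.integer(n), v, a, z, t0, dt, horizon)
  ok <- !is.na(sim$boundary)
  out <- data.frame(rt = sim$rt[ok],
                    boundary = ifelse(sim$boundary[ok] == 1L, "upper", "lower"),
                    stringsAsFactors = FALSE)
  attr(out, "n_timeout") <- sum(!ok)
  out
}

#' Condition-indexed DDM parameters
#'
#' Cell-means parameterization of the 2 x 2 target-expression by
#' required-response design: drift `v` and boundary `a` per cell (named
#' `ss`, `sf`, `fs`, `ff` = target expression then required response,
#' s = smile, f = frown), start bias `z` per target expression (named
#' `s`, `f`), and a single non-decision time `t0`.
#'
#' @param v Named numeric of 4 drift rates.
#' @param a Named numeric of 4 boundary separations (> 0).
#' @param z Named numeric of 2 start biases in (0, 1).
#' @param t0 Non-decision time >= 0 (seconds).
#' @return List of class `ddm_params`.
#' @export
ddm_params <- function(v, a, z, t0 = 0.3) {
  cells <- c("ss", "sf", "fs", "ff")
  stopifnot(all(cells %in% names(v)), all(cells %in% names(a)),
            all(c("s", "f") %in% names(z)))
  if (any(a <= 0)) stop("boundary separation must be positive")
  if (any(z <= 0 | z >= 1)) stop("z must be in (0, 1)")
  if (t0 < 0) stop("t0 must be non-negative")
  if (any(!is.finite(v))) stop("drift must be finite")
  structure(list(v = v[cells], a = a[cells], z = z[c("s", "f")], t0 = t0),
            class = "ddm_params")
}

# design-cell label for target expression x required response
ddm_cell <- function(target_expression, required_response) {
  paste0(substr(target_expression, 1, 1), substr(required_response, 1, 1))
}

#' DDM log likelihood of response-coded observations
#'
#' Sums Wiener log densities at `rt - t0`, with the boundary matching the
#' observed response (upper = smile) and (v, a) indexed by the trial's
#' design cell, z by the target expression. Observations with `rt <= t0`
#' contribute `-Inf` and are counted in the `"n_conflict"` attribute (a
#' data/parameter conflict, not silently dropped).
#'
#' @param observations Data frame with columns `rt` (seconds), `response`,
#'   `target_expression`, `required_response`.
#' @param params A [ddm_params()].
#' @param eps Series truncation tolerance.
#' @return Log likelihood with attribute `n_conflict`.
#' @export
ddm_log_likelihood <- function(observations, params, eps = 1e-7) {
  stopifnot(inherits(params, "ddm_params"))
  cell <- ddm_cell(observations$target_expression,
                   observations$required_response)
  zexp <- substr(observations$target_expression, 1, 1)
  d <- observations$rt - params$t0
  conflict <- d <= 0
  ll <- rep(-Inf, nrow(observations))
  if (any(!conflict)) {
    idx <- which(!conflict)
    ll[idx] <- vapply(idx, function(i) {
      dwiener(d[i], params$v[[cell[i]]], params$a[[cell[i]]],
              params$z[[zexp[i]]],
              boundary = if (observations$response[i] == "smile") "upper" else "lower",
              log = TRUE, eps = eps)
    }, numeric(1))
  }
  out <- sum(ll)
  attr(out, "n_conflict") <- sum(conflict)
  out
}
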