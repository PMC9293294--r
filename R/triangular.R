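#' Triangular distribution: quantile, CDF, mean and sampling
#'
#' Closed-form inverse CDF of the triangular distribution with lower bound
#' `lower`, mode `mode` and upper bound `upper`. Used both as the EF sampler
#' (by inversion of uniforms) and as the analytic oracle for the Monte Carlo
#' quantiles.
#'
#' @param p Probabilities in \[0, 1\].
#' @param lower,mode,upper Distribution parameters with
#'   `lower <= mode <= upper`.
#' @return Quantiles on the EF scale.
#' @examples
#' triangular_quantile(0.975, 0.003, 0.010, 0.030)  # 0.0263258...
#' @export
triangular_quantile <- function(p, lower, mode, upper) {
  check_triangular(lower, mode, upper)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  if (upper == lower) return(rep(lower, length(p)))
  fc <- (mode - lower) / (upper - lower)
  ifelse(p <= fc,
         lower + sqrt(p * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - p) * (upper - lower) * (upper - mode)))
}

#' @rdname triangular_quantile
#' @param q Quantiles on the EF scale.
#' @export
triangular_cdf <- function(q, lower, mode, upper) {
  check_triangular(lower, mode, upper)
  if (upper == lower) return(as.numeric(q >= lower))
  out <- numeric(length(q))
  left <- q <= mode
  denom_l <- (upper - lower) * (mode - lower)
  denom_r <- (upper - lower) * (upper - mode)
  out[left] <- if (denom_l > 0) (q[left] - lower)^2 / denom_l else as.numeric(q[left] >= lower)
  out[!left] <- if (denom_r > 0) 1 - (upper - q[!left])^2 / denom_r else 1
  pmin(pmax(out, 0), 1)
}

#' @rdname triangular_quantile
#' @export
triangular_mean <- function(lower, mode, upper) {
  check_triangular(lower, mode, upper)
  (lower + mode + upper) / 3
}

#' @rdname triangular_quantile
#' @param n Number of draws.
#' @export
rtriangular <- function(n, lower, mode, upper) {
  triangular_quantile(stats::runif(n), lower, mode, upper)
}

check_triangular <- function(lower, mode, upper) {
  stopifnot(length(lower) == 1, length(mode) == 1, length(upper) == 1)
  if (is.na(lower) || is.na(mode) || is.na(upper) ||
      !(lower <= mode && mode <= upper)) {
    stop("triangular parameters must satisfy lower <= mode <= upper",
         call. = FALSE)
  }
  invisible(TRUE)
}
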