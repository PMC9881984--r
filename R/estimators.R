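#' Summary-statistic MR estimators: ratio, IVW, Egger
#'
#' Estimate the causal effect of the exposure on the outcome from per-SNP
#' summary statistics.
#'
#' @section Methods:
#' \describe{
#'   \item{ratio}{For a single instrument, `beta_EO = beta_XO / beta_XE`,
#'     with first-order delta-method standard error `se_XO / |beta_XE|`.}
#'   \item{ivw}{Fixed-effect inverse-variance weighting of the per-SNP
#'     ratios with weights `(beta_XE / se_XO)^2` — equivalently, weighted
#'     regression of `beta_XO` on `beta_XE` through the origin with weights
#'     `1/se_XO^2`. With one instrument this reduces exactly to the ratio
#'     estimator.}
#'   \item{egger}{Weighted least squares of `beta_XO` on `beta_XE` with an
#'     intercept (weights `1/se_XO^2`), after orienting every instrument so
#'     `beta_XE >= 0`. The slope estimates `beta_EO`; the intercept captures
#'     directional pleiotropy. Requires at least 3 instruments. Standard
#'     errors use the fixed-effect covariance `(X'WX)^{-1}`, consistent with
#'     the fixed-effect IVW.}
#' }
#' P-values are two-sided normal.
#'
#' @param stats An `mr_summary_stats` data frame restricted to the chosen
#'   instruments (see [select_instruments()]).
#' @return An object of class `"mr_estimate"`: a list with `beta_EO`, `se`,
#'   `p_value`, `method`, `n_instruments`, and for Egger also `intercept`
#'   and `intercept_se`.
#' @name mr_estimators
NULL

new_mr_estimate <- function(beta_EO, se, method, n_instruments,
                            intercept = NULL, intercept_se = NULL) {
  p <- 2 * stats::pnorm(abs(beta_EO / se), lower.tail = FALSE)
  structure(list(beta_EO = beta_EO, se = se, p_value = p, method = method,
                 n_instruments = n_instruments, intercept = intercept,
                 intercept_se = intercept_se),
            class = "mr_estimate")
}

#' @rdname mr_estimators
#' @export
mr_ratio <- function(stats) {
  validate_summary_stats(stats)
  if (nrow(stats) != 1)
    stop("the ratio estimator is defined for a single instrument; got ",
         nrow(stats), call. = FALSE)
  bxe <- stats$beta_exposure
  if (bxe == 0)
    stop("ratio estimate undefined: beta_exposure is zero", call. = FALSE)
  new_mr_estimate(beta_EO = stats$beta_outcome / bxe,
                  se = stats$se_outcome / abs(bxe),
                  method = "ratio", n_instruments = 1L)
}

#' @rdname mr_estimators
#' @export
mr_ivw <- function(stats) {
  validate_summary_stats(stats)
  bad <- stats$beta_exposure == 0
  if (any(bad)) {
    warning(sum(bad), " instrument(s) with beta_exposure = 0 rejected",
            call. = FALSE)
    stats <- stats[!bad, , drop = FALSE]
  }
  if (nrow(stats) < 1) stop("IVW requires >= 1 usable instrument", call. = FALSE)
  bxe <- stats$beta_exposure
  bxo <- stats$beta_outcome
  w <- 1 / stats$se_outcome^2
  denom <- sum(w * bxe^2)
  beta <- sum(w * bxe * bxo) / denom
  new_mr_estimate(beta_EO = beta, se = sqrt(1 / denom),
                  method = "ivw", n_instruments = nrow(stats))
}

#' @rdname mr_estimators
#' @export
mr_egger <- function(stats) {
  validate_summary_stats(stats)
  if (nrow(stats) < 3)
    stop("Egger regression requires >= 3 instruments; got ", nrow(stats),
         call. = FALSE)
  flip <- sign(stats$beta_exposure)
  flip[flip == 0] <- 1
  bxe <- stats$beta_exposure * flip
  bxo <- stats$beta_outcome * flip
  w <- 1 / stats$se_outcome^2
  X <- cbind(1, bxe)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * bxo))
  vc <- solve(xtwx)
  est <- new_mr_estimate(beta_EO = coefs[2], se = sqrt(vc[2, 2]),
                         method = "egger", n_instruments = nrow(stats),
                         intercept = coefs[1], intercept_se = sqrt(vc[1, 1]))
  est
}

#' Compute an MR estimate by method name
#'
#' Dispatch helper used by [mrtwin()] and the benchmark drivers.
#'
#' @param stats Instrument-level `mr_summary_stats`.
#' @param method One of `"ivw"`, `"egger"`, `"ratio"`.
#' @return An `"mr_estimate"`.
#' @export
mr_estimate <- function(stats, method = c("ivw", "egger", "ratio")) {
  method <- match.arg(method)
  switch(method,
         ivw = mr_ivw(stats),
         egger = mr_egger(stats),
         ratio = mr_ratio(stats))
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d instrument%s)\n", x$method,
              x$n_instruments, if (x$n_instruments == 1) "" else "s"))
  cat(sprintf("  beta_EO = %.6g  (se %.3g, p %.3g)\n",
              x$beta_EO, x$se, x$p_value))
  if (!is.null(x$intercept))
    cat(sprintf("  pleiotropy intercept = %.6g (se %.3g)\n",
                x$intercept, x$intercept_se))
  invisible(x)
}
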