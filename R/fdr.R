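#' Multiple-testing adjustment: BH FDR and Storey pFDR q-values
#'
#' `method = "bh"` is the Benjamini-Hochberg step-up adjustment (via
#' [stats::p.adjust()]), which controls the FDR assuming all hypotheses could
#' be null. `method = "storey"` estimates the positive false discovery rate:
#' the null proportion pi0 is estimated as `#\{p > lambda\} / (m (1 - lambda))`
#' on a lambda grid, smoothed with a cubic spline (df = 3) and read off at the
#' largest lambda, clamped to (0, 1]; q-values are then `pi0` times the BH
#' values. Supplying a single `lambda` skips the smoothing and uses the plug-in
#' estimate at that point.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"storey"`.
#' @param lambda grid for the pi0 estimate (storey only); default
#'   `seq(0, 0.95, 0.05)`.
#' @return q-values, same length and order as `p`. For `"storey"` the pi0
#'   estimate is attached as attribute `"pi0"`.
#' @export
adjust_fdr <- function(p, method = c("bh", "storey"),
                       lambda = seq(0, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  bh <- stats::p.adjust(p, method = "BH")
  if (method == "bh") return(bh)
  pi0 <- estimate_pi0(p, lambda)
  structure(pmin(1, pi0 * bh), pi0 = pi0)
}

# Storey pi0 estimator: plug-in on a lambda grid, cubic smoothing spline
# evaluated at max(lambda), clamped to (0, 1].
estimate_pi0 <- function(p, lambda = seq(0, 0.95, by = 0.05)) {
  m <- length(p)
  if (length(lambda) == 1) {
    pi0 <- sum(p > lambda) / (m * (1 - lambda))
  } else {
    lambda <- sort(lambda)
    pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  }
  min(1, max(pi0, .Machine$double.eps))
}
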