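#' Voxel-overlap agreement between two segmentations
#'
#' Dice's similarity coefficient `DSC = 2|A ∩ M| / (|A| + |M|)`, delineation
#' sensitivity (true positive volume fraction) `|A ∩ M| / |M|`, false
#' positive volume fraction `|A \\ M| / |Ω \\ M|`, and delineation
#' specificity (true negative volume fraction) `1 - FPVF`, where `A` is the
#' automatic mask, `M` the reference, and `Ω` the image domain. Specificity
#' is reported for parity but is close to one whenever `Ω \\ M` dwarfs any
#' plausible oversegmentation, and should not be over-interpreted; the
#' returned object carries this caveat in its `note` field.
#'
#' @param auto,manual [binary_mask()]s of equal shape; `manual` is the
#'   reference.
#' @return an object of class `agreement_stats` with fields `dsc`, `sens`,
#'   `spec`, `fpvf`, voxel counts, and `note`.
#' @export
agreement_stats <- function(auto, manual) {
  stopifnot(inherits(auto, "binary_mask"), inherits(manual, "binary_mask"))
  if (!identical(dim(auto$data), dim(manual$data)))
    stop("mask shapes differ")
  A <- auto$data != 0
  M <- manual$data != 0
  nM <- sum(M)
  nOmega <- length(M)
  if (nM == 0) stop("reference mask is empty: DSC and sensitivity undefined")
  if (nOmega == nM) stop("reference covers the whole domain: specificity undefined")
  inter <- sum(A & M)
  fp <- sum(A & !M)
  structure(list(
    dsc = 2 * inter / (sum(A) + nM),
    sens = inter / nM,
    fpvf = fp / (nOmega - nM),
    spec = 1 - fp / (nOmega - nM),
    n_auto = sum(A), n_manual = nM, n_intersection = inter,
    note = "specificity is near 1 whenever the reference background is large; interpret with care"
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> DSC %.4f, sens %.4f, spec %.4f (FPVF %.3g)\n",
              x$dsc, x$sens, x$spec, x$fpvf))
  invisible(x)
}

#' Bland-Altman agreement between two volumetry methods
#'
#' For each subject the point `((v1 + v2) / 2, v1 - v2)` is formed, with
#' `v1` the automatic and `v2` the manual (reference) value, so the
#' difference is automatic minus manual. Mean bias, the sample SD of the
#' differences (n - 1 denominator), and the classic limits of agreement
#' `bias ± 1.96 SD` are reported.
#'
#' @param v_auto,v_manual numeric vectors of equal length `n >= 2`.
#' @return an object of class `bland_altman` with `points` (data frame
#'   average / difference), `mean_bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(v_auto, v_manual) {
  if (length(v_auto) != length(v_manual))
    stop("sequences must have equal length")
  if (length(v_auto) < 2) stop("need at least 2 subject pairs")
  d <- v_auto - v_manual
  a <- (v_auto + v_manual) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    points = data.frame(average = a, difference = d),
    mean_bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    regression = NULL
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias %.4g, SD %.4g, LoA [%.4g, %.4g]\n",
              nrow(x$points), x$mean_bias, x$sd_diff, x$loa_low, x$loa_high))
  if (!is.null(x$regression))
    cat(sprintf("  difference ~ average: D(a) = %.4g + %.4g a (p = %.3g)\n",
                x$regression$diff_fit["intercept", "estimate"],
                x$regression$diff_fit["slope", "estimate"],
                x$regression$diff_fit["slope", "p"]))
  invisible(x)
}

#' Regression-based limits of agreement
#'
#' When the difference between methods varies with the magnitude of the
#' measurement, constant limits are misleading. Following the standard
#' absolute-residual construction, the difference is regressed on the
#' average, `D(a) = b0 + b1 a`; the absolute residuals of that fit are
#' regressed on the average, `R(a) = c0 + c1 a`; and the limits are
#' `D(a) ± 1.96 sqrt(pi/2) R(a)` (the `sqrt(pi/2) ≈ 1.2533` factor converts
#' a mean absolute deviation of a Gaussian into its SD). Whether the slope
#' is significant enough to warrant the regression-based limits is left to
#' the caller.
#'
#' @param ba a [bland_altman()] object with `n >= 3` points.
#' @return `ba` with a `regression` element: coefficient tables (estimate,
#'   p, 95\% CI) for both fits and vectorized `loa_lower(a)` / `loa_upper(a)`
#'   functions.
#' @export
regression_loa <- function(ba) {
  stopifnot(inherits(ba, "bland_altman"))
  a <- ba$points$average
  d <- ba$points$difference
  if (length(a) < 3) stop("need at least 3 points for regression-based limits")
  if (stats::var(a) == 0) stop("all averages equal: regression is rank-deficient")
  fit_d <- linear_regression(a, d)
  res <- d - (fit_d["intercept", "estimate"] + fit_d["slope", "estimate"] * a)
  fit_r <- linear_regression(a, abs(res))
  k <- 1.96 * sqrt(pi / 2)
  dhat <- function(x) fit_d["intercept", "estimate"] +
    fit_d["slope", "estimate"] * x
  rhat <- function(x) fit_r["intercept", "estimate"] +
    fit_r["slope", "estimate"] * x
  ba$regression <- list(
    diff_fit = fit_d, resid_fit = fit_r,
    loa_lower = function(x) dhat(x) - k * rhat(x),
    loa_upper = function(x) dhat(x) + k * rhat(x))
  ba
}

#' Ordinary least-squares simple linear regression
#'
#' OLS of `y` on `x` with two-sided t-tests and 95% confidence intervals for
#' intercept and slope, plus Pearson's r.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @return a coefficient matrix with rows `intercept` / `slope` and columns
#'   `estimate`, `se`, `t`, `p`, `ci_low`, `ci_high`; Pearson's r is attached
#'   as attribute `"r"`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("constant x: design is rank-deficient")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  out <- cbind(estimate = sm[, 1], se = sm[, 2], t = sm[, 3], p = sm[, 4],
               ci_low = ci[, 1], ci_high = ci[, 2])
  rownames(out) <- c("intercept", "slope")
  attr(out, "r") <- stats::cor(x, y)
  out
}

#' Bland-Altman plot with optional regression-based limits
#'
#' @param x a [bland_altman()] object.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.bland_altman <- function(x, ...) {
  a <- x$points$average
  d <- x$points$difference
  graphics::plot(a, d, xlab = "average of methods", ylab = "difference (auto - manual)",
                 ...)
  graphics::abline(h = x$mean_bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  if (!is.null(x$regression)) {
    xs <- seq(min(a), max(a), length.out = 100)
    graphics::lines(xs, x$regression$loa_lower(xs), lty = 3)
    graphics::lines(xs, x$regression$loa_upper(xs), lty = 3)
  }
  invisible(x)
}
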