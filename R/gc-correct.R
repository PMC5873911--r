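#' Fit a GC-bias correction model to binned coverage
#'
#' Sequencing coverage depends smoothly on local GC content. This fits a
#' penalized cubic-regression-spline of per-bin coverage on per-bin GC with a
#' Tweedie error family (variance proportional to mean^1.5) and log link —
#' the standard compound-Poisson model for non-negative, overdispersed read
#' counts — and returns per-bin residuals for all downstream copy-number
#' work. Fitting is per sample: each library carries its own bias curve.
#'
#' @param cov A `binned_coverage` object (raw stage).
#' @param gc Per-bin GC fractions in `[0, 1]` (same grid as `cov`).
#' @param mappability Optional per-bin mappability; bins with value 0 are
#'   excluded from the fit and get `NA` residuals.
#' @param k Spline basis dimension (default 10 knots); smoothness is chosen
#'   by GCV.
#' @param residual_type `"response"` (observed minus fitted, default) or
#'   `"deviance"`.
#' @return An object of class `gc_fit`: list with `fitted` and `residuals`
#'   (full-length, `NA` on excluded bins), `corrected` (coverage rescaled by
#'   the relative fitted bias, `mean(fitted) * observed / fitted` — the track
#'   used downstream, which removes the GC curve while preserving
#'   between-sample copy ratios), `sample_id`, `residual_type` and the
#'   underlying `mgcv::gam` fit.
#' @seealso [filter_bins()], [quantile_normalize()]
#' @export
fit_gc_correction <- function(cov, gc, mappability = NULL, k = 10,
                              residual_type = c("response", "deviance")) {
  residual_type <- match.arg(residual_type)
  stopifnot(inherits(cov, "binned_coverage"))
  y <- cov$values
  if (length(gc) != length(y)) stopf("gc track length does not match coverage")
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stopf("GC fractions must lie in [0, 1]")
  use <- rep(TRUE, length(y))
  if (!is.null(mappability)) use <- mappability > 0
  if (sum(use) < 500) {
    stopf("need >= 500 bins with positive mappability to fit the GC model (have %d)",
          sum(use))
  }
  if (all(y[use] == 0)) stopf("all-zero coverage: nothing to fit")

  df <- data.frame(y = y[use], gc = gc[use])
  if (stats::sd(df$gc) < 1e-8) {
    # degenerate covariate: the curve collapses to the intercept
    fitted_use <- rep(mean(df$y), nrow(df))
    fit <- NULL
  } else {
    fit <- tryCatch(
      mgcv::gam(y ~ s(gc, k = k, bs = "cr"),
                family = mgcv::Tweedie(p = 1.5, link = "log"), data = df),
      error = function(e) stopf("GC model fit failed: %s", conditionMessage(e)))
    if (!fit$converged) {
      stopf("GC model IRLS did not converge (%d iterations)", fit$iter)
    }
    fitted_use <- as.numeric(stats::fitted(fit))
  }
  if (any(fitted_use <= 0)) stopf("GC model produced non-positive fitted means")

  res_use <- if (residual_type == "response" || is.null(fit)) {
    df$y - fitted_use
  } else {
    as.numeric(stats::residuals(fit, type = "deviance"))
  }
  fitted_all <- residuals_all <- corrected_all <- rep(NA_real_, length(y))
  fitted_all[use] <- fitted_use
  residuals_all[use] <- res_use
  # corrected track: coverage rescaled by the relative fitted bias
  # (mean(fitted) * observed / fitted), which removes the GC curve while
  # preserving copy-number ratios between samples
  corrected_all[use] <- mean(fitted_use) * df$y / fitted_use

  out <- list(sample_id = cov$sample_id,
              fitted = fitted_all,
              residuals = residuals_all,
              corrected = binned_coverage(
                cov$sample_id,
                corrected_all,
                "corrected"),
              residual_type = residual_type,
              gam = fit)
  class(out) <- "gc_fit"
  out
}

#' @export
print.gc_fit <- function(x, ...) {
  n <- sum(!is.na(x$residuals))
  cat(sprintf("GC correction fit for '%s' (Tweedie p=1.5, log link)\n",
              x$sample_id))
  cat(sprintf("  %d bins fitted; mean fitted %.2f; residual SD %.2f (%s)\n",
              n, mean(x$fitted, na.rm = TRUE),
              stats::sd(x$residuals, na.rm = TRUE), x$residual_type))
  invisible(x)
}

#' @export
fitted.gc_fit <- function(object, ...) object$fitted

#' @export
residuals.gc_fit <- function(object, ...) object$residuals

#' @export
plot.gc_fit <- function(x, gc = NULL, ...) {
  if (is.null(gc)) {
    if (is.null(x$gam)) stopf("supply the gc track to plot a degenerate fit")
    plot(x$gam, ...)
    return(invisible(x))
  }
  ok <- !is.na(x$fitted)
  graphics::plot(gc[ok], x$fitted[ok] + x$residuals[ok],
                 pch = ".", col = "grey40",
                 xlab = "GC fraction", ylab = "coverage", ...)
  o <- order(gc[ok])
  graphics::lines(gc[ok][o], x$fitted[ok][o], col = "red", lwd = 2)
  invisible(x)
}
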