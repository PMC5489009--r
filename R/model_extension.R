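#' Screen residual correlations against candidate variables
#'
#' Pearson correlation (with two-sided p-value) between the day-level
#' prediction residuals and each candidate column. Following the usual
#' recommendation for subjective human-response studies, candidates with
#' |r| >= `threshold` (default 0.3) are flagged as relevant; no
#' multiple-testing correction is applied. Zero-variance candidates are
#' skipped with a message.
#'
#' @param residuals Day-level residuals (actual minus predicted vote).
#' @param candidates Data frame of candidate variables, one row per day.
#' @param threshold Relevance threshold on |r|.
#' @return A data frame `variable`, `r`, `p`, `relevant`, sorted by
#'   decreasing |r|.
#' @export
screen_residual_correlations <- function(residuals, candidates,
                                         threshold = 0.3) {
  if (length(residuals) < 3) stop("need at least 3 days")
  if (nrow(candidates) != length(residuals))
    stop("candidates must have one row per residual")
  rows <- lapply(names(candidates), function(v) {
    x <- candidates[[v]]
    if (stats::sd(x) == 0 || stats::sd(residuals) == 0) {
      message("screening: skipping zero-variance candidate '", v, "'")
      return(NULL)
    }
    ct <- stats::cor.test(residuals, x)
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value)
  })
  rep <- do.call(rbind, rows)
  if (is.null(rep))
    return(data.frame(variable = character(), r = numeric(),
                      p = numeric(), relevant = logical()))
  rep$relevant <- abs(rep$r) >= threshold
  rep <- rep[order(-abs(rep$r)), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' @rdname screen_residual_correlations
#' @export
post_extension_screen <- screen_residual_correlations

#' Fit the RMOT extension of the PMV model
#'
#' Regresses the day-level residuals (AMV - PMV_met) on the running mean
#' outdoor temperature and stores the affine correction, giving the
#' extended predictor PMV* = PMV_met + b RMOT + c. A negative b means
#' people feel warmer than the heat balance predicts when the recent
#' outdoor climate has been cold, the signature of adaptation.
#'
#' @param residuals Day-level residuals, AMV - PMV_met.
#' @param rmot Running mean outdoor temperature per day, degrees C
#'   (non-constant).
#' @return An object of class `pmv_extension` with `beta_rmot`,
#'   `intercept_rmot`, their 95% confidence intervals, `fitted_on`
#'   (number of days) and the underlying `lm` fit.
#' @export
fit_rmot_extension <- function(residuals, rmot) {
  if (length(residuals) != length(rmot))
    stop("residuals and rmot must have equal length")
  if (stats::sd(rmot) == 0) stop("RMOT is constant; extension is unidentifiable")
  fit <- stats::lm(residuals ~ rmot)
  ci <- stats::confint(fit, level = 0.95)
  out <- list(
    beta_rmot = unname(stats::coef(fit)[2]),
    intercept_rmot = unname(stats::coef(fit)[1]),
    beta_rmot_ci95 = unname(ci["rmot", ]),
    intercept_rmot_ci95 = unname(ci["(Intercept)", ]),
    beta_pref = NULL,
    intercept_pref = NULL,
    fitted_on = length(residuals),
    fit_rmot = fit
  )
  class(out) <- "pmv_extension"
  out
}

#' Apply the extended predictors
#'
#' `predict_pmv_star()` applies the RMOT correction:
#' PMV* = PMV_met + beta_rmot RMOT + intercept.
#' `predict_pmv_star_star()` additionally applies the thermal-preference
#' correction: PMV** = PMV* + beta_pref Preference + intercept. PMV** is
#' a diagnostic rather than a predictive model, since preference is not
#' known in advance.
#'
#' @param pmv_met Day-level PMV at the median calibrated metabolic rate.
#' @param pmv_star Day-level PMV*.
#' @param rmot Running mean outdoor temperature per day, degrees C.
#' @param preference Day-mean thermal preference vote (warmer-positive).
#' @param model A fitted `pmv_extension`.
#' @return The corrected predictor, same length as the inputs.
#' @export
predict_pmv_star <- function(pmv_met, rmot, model) {
  stopifnot(inherits(model, "pmv_extension"))
  pmv_met + model$beta_rmot * rmot + model$intercept_rmot
}

#' @rdname predict_pmv_star
#' @export
predict_pmv_star_star <- function(pmv_star, preference, model) {
  stopifnot(inherits(model, "pmv_extension"))
  if (is.null(model$beta_pref))
    stop("model has no preference stage; call fit_preference_extension() first")
  pmv_star + model$beta_pref * preference + model$intercept_pref
}

#' Fit the thermal-preference extension
#'
#' Regresses the PMV* residuals (AMV - PMV*) on the day-mean thermal
#' preference vote and adds the second affine stage to the model,
#' giving PMV** = PMV* + b Preference + c. With preference coded
#' warmer-positive, b is expected to be negative: respondents who feel
#' cold prefer a warmer environment.
#'
#' @param model A `pmv_extension` from [fit_rmot_extension()].
#' @param residuals_star Day-level residuals AMV - PMV*.
#' @param preference Day-mean preference vote per day (non-constant).
#' @return The updated `pmv_extension`.
#' @export
fit_preference_extension <- function(model, residuals_star, preference) {
  stopifnot(inherits(model, "pmv_extension"))
  if (length(residuals_star) != length(preference))
    stop("residuals_star and preference must have equal length")
  if (stats::sd(preference) == 0)
    stop("preference is constant; extension is unidentifiable")
  fit <- stats::lm(residuals_star ~ preference)
  ci <- stats::confint(fit, level = 0.95)
  model$beta_pref <- unname(stats::coef(fit)[2])
  model$intercept_pref <- unname(stats::coef(fit)[1])
  model$beta_pref_ci95 <- unname(ci["preference", ])
  model$intercept_pref_ci95 <- unname(ci["(Intercept)", ])
  model$fit_pref <- fit
  model
}

#' @export
print.pmv_extension <- function(x, ...) {
  cat("Extended PMV model (fitted on", x$fitted_on, "survey days)\n")
  cat(sprintf("  PMV*  = PMV_met %+.4f RMOT %+.4f\n",
              x$beta_rmot, x$intercept_rmot))
  if (!is.null(x$beta_pref))
    cat(sprintf("  PMV** = PMV*  %+.4f Preference %+.4f\n",
                x$beta_pref, x$intercept_pref))
  invisible(x)
}

#' Serialize an extended model to structured text
#'
#' Coefficients, confidence intervals and fit metadata are written as
#' JSON; `read_extension()` restores a `pmv_extension` usable for
#' prediction (the `lm` objects themselves are not serialized).
#'
#' @param model A `pmv_extension`.
#' @param path File path.
#' @param screening Optional screening report data frame to embed.
#' @export
write_extension <- function(model, path, screening = NULL) {
  payload <- model[c("beta_rmot", "intercept_rmot", "beta_rmot_ci95",
                     "intercept_rmot_ci95", "beta_pref", "intercept_pref",
                     "fitted_on")]
  payload <- payload[!vapply(payload, is.null, logical(1))]
  if (!is.null(screening)) payload$screening_report <- screening
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_extension
#' @export
read_extension <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    beta_rmot = p$beta_rmot, intercept_rmot = p$intercept_rmot,
    beta_rmot_ci95 = p$beta_rmot_ci95,
    intercept_rmot_ci95 = p$intercept_rmot_ci95,
    beta_pref = p$beta_pref, intercept_pref = p$intercept_pref,
    fitted_on = p$fitted_on
  )
  class(out) <- "pmv_extension"
  out
}
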