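#' Stratify a predictor by a DMS score
#'
#' Joins a variant-keyed predictor table to a DMS score table, splits the
#' variants into two strata at the score threshold (score > threshold vs
#' score <= threshold), and summarises the predictor per stratum with its
#' mean and a normal-approximation 95\% confidence interval
#' (mean +/- 1.96 se).
#'
#' @param dms data.frame keyed by variant (position, wt_aa, alt_aa) with
#'   the stratifying score column.
#' @param predictor data.frame keyed by variant with the predictor column.
#' @param score_field Name of the predictor column (e.g. "vep_score",
#'   "ddg_active").
#' @param dms_field Name of the DMS score column used to stratify.
#' @param threshold Class boundary; scores exactly at the threshold fall
#'   in the lower ("reduced") stratum.
#' @return List of class \code{dms_strata}: \code{summary} (data.frame
#'   with stratum, n, mean, ci_lo, ci_hi), \code{difference}
#'   (reduced minus maintained stratum mean), and \code{data} (the joined
#'   per-variant table with columns value, stratum, position).
#' @export
stratify_by_dms <- function(dms, predictor, score_field,
                            dms_field = "log2FoldChange", threshold = 0) {
  if (!score_field %in% names(predictor))
    stop("predictor table has no column '", score_field, "'")
  if (!dms_field %in% names(dms))
    stop("DMS table has no column '", dms_field, "'")
  kd <- variant_key(dms)
  kp <- variant_key(predictor)
  common <- intersect(kd, kp)
  if (length(common) == 0)
    stop("stratification error: DMS and predictor tables share no variants")
  id <- match(common, kd); ip <- match(common, kp)
  dropped <- (length(kd) - length(common)) + (length(kp) - length(common))
  dat <- data.frame(position = dms$position[id],
                    value = predictor[[score_field]][ip],
                    score = dms[[dms_field]][id])
  dat <- dat[is.finite(dat$value) & is.finite(dat$score), , drop = FALSE]
  dat$stratum <- factor(ifelse(dat$score > threshold, "maintained", "reduced"),
                        levels = c("maintained", "reduced"))
  tab <- table(dat$stratum)
  if (any(tab < 2))
    stop("stratification error: stratum '",
         names(tab)[which(tab < 2)[1]], "' has fewer than 2 variants")
  sm <- do.call(rbind, lapply(levels(dat$stratum), function(s) {
    v <- dat$value[dat$stratum == s]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(stratum = s, n = length(v), mean = mean(v),
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = sm,
                 difference = sm$mean[sm$stratum == "reduced"] -
                   sm$mean[sm$stratum == "maintained"],
                 n_dropped = dropped, data = dat),
            class = "dms_strata")
}

#' Mixed-model test of a stratum difference with random positional effects
#'
#' Fits \code{value ~ stratum + (1 | position)} by REML and reports the
#' stratum fixed effect with its Wald standard error and two-sided normal
#' p value. Variants at the same position share a random intercept, so the
#' test is corrected for positional effects rather than treating the 19
#' substitutions per site as independent. When the random-effect variance
#' estimates to zero (singular fit), the model falls back to ordinary
#' least squares with a warning.
#'
#' @param value Numeric predictor values.
#' @param stratum Two-level factor (reference level first); the returned
#'   coefficient is the second level's mean shift, so with levels
#'   c("maintained", "reduced") a positive estimate means the reduced/
#'   destabilized stratum has the higher predictor value.
#' @param position Integer positions (random-intercept grouping).
#' @return List with \code{estimate}, \code{se}, \code{p},
#'   \code{random_sd}, \code{method} ("lmm" or "ols").
#' @export
mixed_model_test <- function(value, stratum, position) {
  stratum <- droplevels(as.factor(stratum))
  if (nlevels(stratum) != 2)
    stop("stratum must have exactly 2 levels with data")
  if (length(unique(position)) < 2)
    stop("model error: need at least 2 positions")
  dat <- data.frame(value = value, stratum = stratum,
                    position = factor(position))
  fit <- suppressMessages(
    lme4::lmer(value ~ stratum + (1 | position), data = dat, REML = TRUE))
  random_sd <- sqrt(unname(lme4::VarCorr(fit)$position[1]))
  if (lme4::isSingular(fit, tol = 1e-5) || random_sd < 1e-8) {
    warning("random positional variance estimated at zero; ",
            "falling back to ordinary least squares")
    ols <- stats::lm(value ~ stratum, data = dat)
    est <- unname(stats::coef(ols)[2])
    se <- unname(sqrt(diag(stats::vcov(ols)))[2])
    p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(est / se)) else NA_real_
    return(list(estimate = est, se = se, p = p,
                random_sd = 0, method = "ols"))
  }
  cf <- summary(fit)$coefficients
  est <- unname(cf[2, "Estimate"])
  se <- unname(cf[2, "Std. Error"])
  p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(est / se)) else NA_real_
  list(estimate = est, se = se, p = p,
       random_sd = random_sd, method = "lmm")
}

#' Compare ddG stratifications across serpin conformations
#'
#' Runs the stratified summary and the positional mixed-model test for the
#' ddG of both the active and latent conformations, stratifying either by
#' the inhibition score (0 h) or the refined functional stability score
#' (48 h). The paired layout mirrors the side-by-side reporting of
#' stability-predictor comparisons: nonfunctional variants are expected to
#' carry elevated ddG in both conformations (misfolding), while
#' stabilization of the latency transition is expected to be invisible to
#' equilibrium stability predictions.
#'
#' @param dms DMS score table; for \code{stratify_by = "stability"} pass
#'   the refined table (rows with \code{refined == FALSE} are dropped).
#' @param ddg Predictor table with columns \code{ddg_active} and
#'   \code{ddg_latent}.
#' @param stratify_by "inhibition" (0 h score) or "stability" (48 h
#'   refined functional stability score).
#' @param threshold Class boundary (default 0).
#' @return data.frame with one row per conformation: stratum means, 95\%
#'   CIs and n, the mixed-model estimate, se and p, and the method used.
#' @export
compare_conformations <- function(dms, ddg,
                                  stratify_by = c("inhibition", "stability"),
                                  threshold = 0) {
  stratify_by <- match.arg(stratify_by)
  if (!all(c("ddg_active", "ddg_latent") %in% names(ddg)))
    stop("ddG table must carry both conformations (ddg_active, ddg_latent)")
  if (stratify_by == "inhibition") {
    field <- if ("inhibition_score" %in% names(dms)) "inhibition_score"
             else "log2FoldChange"
  } else {
    if (!"functional_stability_score" %in% names(dms))
      stop("stability stratification needs a refined score table")
    if ("refined" %in% names(dms)) dms <- dms[dms$refined, , drop = FALSE]
    field <- "functional_stability_score"
  }
  rows <- lapply(c("ddg_active", "ddg_latent"), function(conf) {
    st <- stratify_by_dms(dms, ddg, conf, dms_field = field,
                          threshold = threshold)
    mm <- withCallingHandlers(
      mixed_model_test(st$data$value, st$data$stratum, st$data$position),
      warning = function(w) invokeRestart("muffleWarning"))
    sm <- st$summary
    hi <- sm[sm$stratum == "maintained", ]
    lo <- sm[sm$stratum == "reduced", ]
    data.frame(conformation = sub("ddg_", "", conf),
               stratified_by = stratify_by,
               n_maintained = hi$n, mean_maintained = hi$mean,
               ci_lo_maintained = hi$ci_lo, ci_hi_maintained = hi$ci_hi,
               n_reduced = lo$n, mean_reduced = lo$mean,
               ci_lo_reduced = lo$ci_lo, ci_hi_reduced = lo$ci_hi,
               estimate = mm$estimate, se = mm$se, p = mm$p,
               method = mm$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
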