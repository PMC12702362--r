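#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over variants
#' with positive counts in every sample, of the ratio of the sample's
#' count to the geometric mean of the variant's counts across samples.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Integer matrix, variants x samples (>= 2 samples).
#' @return Named numeric vector of strictly positive size factors.
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be nonnegative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("normalization error: no variant has positive counts in every sample")
  logc <- log(counts[all_pos, , drop = FALSE])
  log_geo <- rowMeans(logc)
  sf <- exp(apply(logc - log_geo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# Fit a mean-dispersion trend alpha(mu) = a0 + a1/mu on variants with a
# positive raw moment estimate; coefficients clipped so the trend is
# nonnegative over the observed means.
fit_dispersion_trend <- function(mu, alpha_hat) {
  use <- alpha_hat > 0 & mu > 0
  if (sum(use) < 10) {
    med <- stats::median(alpha_hat[alpha_hat > 0])
    if (!is.finite(med)) med <- 0
    return(function(m) rep(med, length(m)))
  }
  fit <- stats::lm(alpha_hat[use] ~ I(1 / mu[use]))
  a0 <- max(0, unname(stats::coef(fit)[1]))
  a1 <- max(0, unname(stats::coef(fit)[2]))
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Method-of-moments dispersion estimates
#'
#' Per-variant negative-binomial overdispersion estimated from size-factor
#' normalized counts: within each condition with at least two replicates,
#' \code{alpha_hat = max(0, (s^2 - mean) / mean^2)}; estimates are pooled
#' across conditions (weighted by residual degrees of freedom), then shrunk
#' 50/50 toward a fitted mean-dispersion trend and floored at 1e-8. If no
#' condition has replicates, a configured prior dispersion is returned for
#' every variant with a warning.
#'
#' @param counts Integer matrix, variants x samples.
#' @param size_factors Per-sample size factors.
#' @param condition Character/factor vector of per-sample condition labels.
#' @param prior_dispersion Fallback dispersion for unreplicated designs.
#' @return Numeric vector of per-variant dispersions (>= 1e-8).
#' @export
estimate_dispersions <- function(counts, size_factors, condition,
                                 prior_dispersion = 0.1) {
  counts <- as.matrix(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  condition <- as.character(condition)
  reps <- table(condition)
  usable <- names(reps)[reps >= 2]
  if (length(usable) == 0) {
    warning("no condition has >= 2 replicates; returning prior dispersion ",
            prior_dispersion, " for every variant")
    return(rep(prior_dispersion, nrow(counts)))
  }
  num <- den <- rep(0, nrow(counts))
  for (cond in usable) {
    sub <- norm[, condition == cond, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    a <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
    w <- ncol(sub) - 1
    num <- num + w * a
    den <- den + w
  }
  alpha_hat <- num / den
  mu <- rowMeans(norm)
  trend <- fit_dispersion_trend(mu, alpha_hat)
  pmax(1e-8, 0.5 * alpha_hat + 0.5 * trend(mu))
}

#' Score a selection contrast with a negative-binomial Wald test
#'
#' Turns a variant count table into per-variant enrichment records for one
#' contrast (selected condition over input condition): size factors by
#' median-of-ratios over the contrast's samples, log2 fold change of
#' pseudocounted normalized condition means, a delta-method standard error
#' from the negative-binomial mean-variance relation, a two-sided Wald p
#' value, and Benjamini-Hochberg adjustment computed over the variants
#' passing the baseMean filter only (others carry \code{padj = NA}).
#'
#' @param counts Integer matrix, variants x samples; row names are variant
#'   keys ("I91L") or a \code{variants} data.frame may be supplied.
#' @param samples data.frame with columns \code{sample}, \code{condition}
#'   matching \code{colnames(counts)}.
#' @param contrast Length-2 character vector:
#'   c(selected_condition, input_condition).
#' @param base_mean_threshold Minimum baseMean (mean normalized count over
#'   the contrast's samples) for a variant to enter the FDR computation.
#' @param pseudocount Added to both normalized condition means before the
#'   log ratio; keeps fully depleted variants finite.
#' @param variants Optional data.frame (position, wt_aa, alt_aa) keying the
#'   rows; parsed from row names when absent.
#' @param prior_dispersion Passed to \code{\link{estimate_dispersions}}.
#' @return data.frame with columns position, wt_aa, alt_aa, baseMean,
#'   log2FoldChange, lfcSE, pvalue, padj, dispersion, passed_filter.
#' @export
score_contrast <- function(counts, samples, contrast,
                           base_mean_threshold = 50, pseudocount = 0.5,
                           variants = NULL, prior_dispersion = 0.1) {
  counts <- as.matrix(counts)
  if (length(contrast) != 2)
    stop("contrast must be c(selected_condition, input_condition)")
  if (!all(contrast %in% samples$condition))
    stop("input error: contrast condition missing from sample table: ",
         paste(setdiff(contrast, samples$condition), collapse = ", "))
  keep <- samples$condition %in% contrast
  smp <- samples[keep, , drop = FALSE]
  counts <- counts[, match(smp$sample, colnames(counts)), drop = FALSE]

  if (is.null(variants)) {
    if (is.null(rownames(counts)))
      stop("counts must have variant row names or a variants table")
    variants <- parse_variants(rownames(counts))
  }

  sf <- compute_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  alpha <- estimate_dispersions(counts, sf, smp$condition,
                                prior_dispersion = prior_dispersion)

  sel <- smp$condition == contrast[1]
  inp <- smp$condition == contrast[2]
  q_sel <- rowMeans(norm[, sel, drop = FALSE])
  q_inp <- rowMeans(norm[, inp, drop = FALSE])
  base_mean <- rowMeans(norm)

  # Delta-method variance of each condition mean on the normalized scale:
  # Var(K_ij / s_j) = q_i / s_j + alpha_i * q_i^2.
  var_mean <- function(q, idx) {
    s <- sf[idx]
    sapply(seq_along(q), function(i)
      sum(q[i] / s + alpha[i] * q[i]^2) / length(s)^2)
  }
  v_sel <- var_mean(q_sel, which(sel))
  v_inp <- var_mean(q_inp, which(inp))

  log2fc <- log2(q_sel + pseudocount) - log2(q_inp + pseudocount)
  se <- sqrt(v_sel / (q_sel + pseudocount)^2 +
               v_inp / (q_inp + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(z))
  pvalue[se == 0] <- 1

  passed <- base_mean >= base_mean_threshold
  padj <- rep(NA_real_, length(pvalue))
  padj[passed] <- stats::p.adjust(pvalue[passed], method = "BH")

  res <- data.frame(position = variants$position, wt_aa = variants$wt_aa,
                    alt_aa = variants$alt_aa, baseMean = base_mean,
                    log2FoldChange = log2fc, lfcSE = se, pvalue = pvalue,
                    padj = padj, dispersion = alpha, passed_filter = passed,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Sample-level PCA of the enrichment space
#'
#' Principal component analysis of log2(normalized count + 1) with samples
#' as observations, centred per variant. Used as a replicate-level QC view:
#' input, 0 h-selected and 48 h-selected libraries should separate on the
#' first components.
#'
#' @param counts Integer matrix, variants x samples (>= 3 samples).
#' @param size_factors Optional; computed by median-of-ratios when absent.
#' @return List with \code{coords} (samples x PCs) and
#'   \code{var_explained} (fraction of variance per component, sums to 1).
#' @export
sample_pca <- function(counts, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("QC error: sample PCA needs at least 3 samples")
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  x <- t(log2(sweep(counts, 2, size_factors, "/") + 1))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x, var_explained = var_explained)
}
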