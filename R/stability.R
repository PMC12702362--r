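#' Post hoc refinement of functional stability scores
#'
#' The 48 h screen's depleted class mixes variants that lost inhibitory
#' activity outright with variants that merely transitioned to latency
#' faster. Refinement removes from the 48 h table every variant whose 0 h
#' inhibition score is below zero, leaving only variants that at least
#' maintain protease inhibition; a score of exactly zero is retained.
#'
#' @param scores_0h,scores_48h Enrichment tables from
#'   \code{\link{score_contrast}} for the 0 h and 48 h contrasts. Only
#'   variants passing the baseMean filter in a screen count as scored in
#'   that screen.
#' @return data.frame keyed by variant with columns \code{position},
#'   \code{wt_aa}, \code{alt_aa}, \code{inhibition_score},
#'   \code{functional_stability_score}, \code{padj_0h}, \code{padj_48h},
#'   \code{refined}; one row per variant scored in both screens.
#' @export
refine_functional_stability <- function(scores_0h, scores_48h) {
  s0 <- scores_0h[scores_0h$passed_filter, , drop = FALSE]
  s48 <- scores_48h[scores_48h$passed_filter, , drop = FALSE]
  k0 <- variant_key(s0)
  k48 <- variant_key(s48)
  common <- intersect(k0, k48)
  if (length(common) == 0)
    stop("input error: the two screens share no scored variants")
  i0 <- match(common, k0)
  i48 <- match(common, k48)
  out <- data.frame(position = s0$position[i0], wt_aa = s0$wt_aa[i0],
                    alt_aa = s0$alt_aa[i0],
                    inhibition_score = s0$log2FoldChange[i0],
                    functional_stability_score = s48$log2FoldChange[i48],
                    padj_0h = s0$padj[i0], padj_48h = s48$padj[i48],
                    stringsAsFactors = FALSE)
  out$refined <- out$inhibition_score >= 0
  out
}

#' Positional mutational acceptance scores
#'
#' Aggregates refined functional stability scores at each position. The
#' default aggregate is the mean; the sum is available as an alternative.
#' Positions with no refined variant are absent from the output.
#'
#' @param scores Refined score table from
#'   \code{\link{refine_functional_stability}} (rows with
#'   \code{refined == FALSE} are dropped), or any data.frame with columns
#'   \code{position} and \code{functional_stability_score}.
#' @param aggregate "mean" (default) or "sum".
#' @return data.frame with columns \code{position},
#'   \code{mutational_acceptance}, \code{n_variants}, ordered by position.
#' @export
positional_acceptance <- function(scores, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if ("refined" %in% names(scores))
    scores <- scores[scores$refined, , drop = FALSE]
  if (nrow(scores) == 0) stop("no refined variants to aggregate")
  fun <- if (aggregate == "mean") mean else sum
  agg <- tapply(scores$functional_stability_score, scores$position, fun)
  n <- tapply(scores$functional_stability_score, scores$position, length)
  pos <- as.integer(names(agg))
  ord <- order(pos)
  data.frame(position = pos[ord],
             mutational_acceptance = as.numeric(agg)[ord],
             n_variants = as.integer(n)[ord])
}

#' LOWESS smoothing of a positional series
#'
#' Locally weighted linear regression evaluated at each observed position:
#' for each point, the \code{window_points} nearest positions (by distance
#' along the sequence) are fit with tricube weights and local degree 1; no
#' robustness iterations are applied. Positions with absent values are
#' excluded from neighbour sets, so gaps in the screen do not contribute.
#'
#' @param position Integer vector of positions with values.
#' @param value Numeric vector of the same length.
#' @param window_points Number of nearest neighbours in each local fit.
#' @return data.frame with columns \code{position}, \code{lowess_value}.
#' @export
lowess_smooth <- function(position, value, window_points = 20) {
  ok <- is.finite(value)
  position <- position[ok]; value <- value[ok]
  n <- length(position)
  if (n < window_points)
    stop("smoothing error: need at least ", window_points,
         " positions with values")
  ord <- order(position)
  x <- as.numeric(position[ord]); y <- value[ord]
  k <- as.integer(window_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(k)]
    dmax <- max(d[idx])
    w <- if (dmax == 0) rep(1, k) else (1 - pmin(1, d[idx] / dmax)^3)^3
    w[w < 0] <- 0
    xs <- x[idx]; ys <- y[idx]
    sw <- sum(w)
    xbar <- sum(w * xs) / sw
    ybar <- sum(w * ys) / sw
    sxx <- sum(w * (xs - xbar)^2)
    if (sxx > 0) {
      b <- sum(w * (xs - xbar) * (ys - ybar)) / sxx
      out[i] <- ybar + b * (x[i] - xbar)
    } else {
      out[i] <- ybar
    }
  }
  data.frame(position = as.integer(x), lowess_value = out)
}

#' Call stabilizing and destabilizing regions from a smoothed profile
#'
#' Classifies each position from its LOWESS value: destabilizing where the
#' value is below zero, stabilizing where it reaches the upper threshold
#' (by default the 75th percentile of the LOWESS series; alternatively its
#' mean), neutral otherwise. Contiguous runs of a class are merged into
#' 1-based inclusive intervals.
#'
#' @param position,lowess_value The smoothed profile.
#' @param upper_quantile Quantile (linear-interpolation definition) of the
#'   LOWESS series used as the stabilizing threshold.
#' @param lower Threshold below which positions are destabilizing.
#' @param upper_type "percentile" (default) or "mean".
#' @return List with \code{classes} (data.frame position, lowess_value,
#'   region_class), \code{intervals} (data.frame region_class, start, end),
#'   and \code{upper_threshold}.
#' @export
call_regions <- function(position, lowess_value, upper_quantile = 0.75,
                         lower = 0, upper_type = c("percentile", "mean")) {
  upper_type <- match.arg(upper_type)
  if (length(position) == 0) stop("no lowess values supplied")
  upper <- if (upper_type == "percentile") {
    as.numeric(stats::quantile(lowess_value, upper_quantile, type = 7))
  } else {
    mean(lowess_value)
  }
  cls <- ifelse(lowess_value < lower, "destabilizing",
                ifelse(lowess_value >= upper, "stabilizing", "neutral"))
  ord <- order(position)
  classes <- data.frame(position = as.integer(position[ord]),
                        lowess_value = lowess_value[ord],
                        region_class = cls[ord], stringsAsFactors = FALSE)
  # Merge contiguous same-class runs (gaps in position break a run).
  runs <- rle(paste(classes$region_class,
                    cumsum(c(0, diff(classes$position) != 1L))))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  intervals <- data.frame(
    region_class = classes$region_class[starts],
    start = classes$position[starts],
    end = classes$position[ends], stringsAsFactors = FALSE)
  intervals <- intervals[intervals$region_class != "neutral", , drop = FALSE]
  rownames(intervals) <- NULL
  list(classes = classes, intervals = intervals, upper_threshold = upper)
}

#' Jaccard overlap between two interval sets
#'
#' Position-level Jaccard index between the unions of two sets of 1-based
#' inclusive intervals; used to compare called stabilizing regions with a
#' planted or published region set.
#'
#' @param a,b data.frames with columns \code{start}, \code{end}.
#' @return Jaccard index in [0, 1].
#' @export
interval_jaccard <- function(a, b) {
  expand <- function(d) {
    if (nrow(d) == 0) return(integer(0))
    unique(unlist(Map(seq.int, d$start, d$end)))
  }
  pa <- expand(a); pb <- expand(b)
  u <- length(union(pa, pb))
  if (u == 0) return(NA_real_)
  length(intersect(pa, pb)) / u
}
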