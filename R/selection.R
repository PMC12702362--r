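#' Normalized position counts
#'
#' For each position, the fraction of scored substitutions whose log2
#' enrichment score is above zero: the screen-level measure of how
#' permissive a position is with respect to the selected function. For the
#' 48 h screen the refined table (variants retaining inhibition at 0 h)
#' is the intended input.
#'
#' @param scores data.frame with columns \code{position} and the score
#'   column; rows with \code{refined == FALSE} are dropped when a
#'   \code{refined} column is present.
#' @param score_field Name of the score column.
#' @return data.frame with columns \code{position}, \code{npc} (in [0,1]),
#'   \code{n_scored}; positions with no scored variant are absent.
#' @export
normalized_position_counts <- function(scores, score_field = "log2FoldChange") {
  if (!score_field %in% names(scores))
    stop("score table has no column '", score_field, "'")
  if ("refined" %in% names(scores))
    scores <- scores[scores$refined, , drop = FALSE]
  if ("passed_filter" %in% names(scores))
    scores <- scores[scores$passed_filter, , drop = FALSE]
  s <- scores[[score_field]]
  ok <- is.finite(s)
  scores <- scores[ok, , drop = FALSE]; s <- s[ok]
  npc <- tapply(s > 0, scores$position, mean)
  n <- tapply(s, scores$position, length)
  pos <- as.integer(names(npc))
  ord <- order(pos)
  data.frame(position = pos[ord], npc = as.numeric(npc)[ord],
             n_scored = as.integer(n)[ord])
}

#' Regression of conservation on normalized position counts
#'
#' Ordinary least squares of the per-position conservation score on the
#' normalized position count, with a two-sided t test of the slope. A
#' positive slope indicates purifying selection on the screened function:
#' positions permissive in the screen are also evolutionarily labile.
#'
#' @param npc data.frame from \code{\link{normalized_position_counts}}.
#' @param conservation data.frame with columns \code{position},
#'   \code{conservation}.
#' @return List with \code{slope}, \code{intercept}, \code{R2}, \code{p},
#'   \code{n}.
#' @export
conservation_regression <- function(npc, conservation) {
  m <- merge(npc, conservation, by = "position")
  m <- m[is.finite(m$npc) & is.finite(m$conservation), , drop = FALSE]
  if (nrow(m) < 3)
    stop("regression error: need at least 3 positions with both values")
  if (stats::var(m$npc) == 0)
    stop("regression error: zero variance in normalized position counts")
  if (stats::var(m$conservation) == 0)
    return(list(slope = 0, intercept = m$conservation[1], R2 = 0, p = 1,
                n = nrow(m)))
  fit <- stats::lm(conservation ~ npc, data = m)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       R2 = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = nrow(m))
}

#' Median-quadrant segmentation and one-way conservation ANOVA
#'
#' Splits positions at the medians of the 0 h and 48 h normalized position
#' counts into four quadrants (Cartesian convention with x = 0 h npc,
#' y = 48 h npc): Q1 = (x > med, y > med), Q2 = (x <= med, y > med),
#' Q3 = (x <= med, y <= med), Q4 = (x > med, y <= med). Positions exactly
#' at a median fall in the low half. Q4 is thus inhibition-permissive but
#' stability-constrained, Q3 constrained for both. Conservation is
#' compared across quadrants with a one-way ANOVA followed by Tukey's HSD
#' (Tukey-Kramer for unequal group sizes).
#'
#' @param npc_0h,npc_48h data.frames from
#'   \code{\link{normalized_position_counts}}; only positions present in
#'   both enter the analysis.
#' @param conservation data.frame with columns \code{position},
#'   \code{conservation}.
#' @return List with \code{data} (position, npc_0h, npc_48h, conservation,
#'   quadrant), \code{medians}, \code{group_means}, \code{anova} (F, df,
#'   p), and \code{tukey} (data.frame comparison, diff, p_adj).
#' @export
quadrant_analysis <- function(npc_0h, npc_48h, conservation) {
  m <- merge(merge(stats::setNames(npc_0h[c("position", "npc")],
                                   c("position", "npc_0h")),
                   stats::setNames(npc_48h[c("position", "npc")],
                                   c("position", "npc_48h")),
                   by = "position"),
             conservation, by = "position")
  med_x <- stats::median(m$npc_0h)
  med_y <- stats::median(m$npc_48h)
  hi_x <- m$npc_0h > med_x
  hi_y <- m$npc_48h > med_y
  m$quadrant <- ifelse(hi_x & hi_y, "Q1",
                       ifelse(!hi_x & hi_y, "Q2",
                              ifelse(!hi_x & !hi_y, "Q3", "Q4")))
  tab <- table(factor(m$quadrant, levels = paste0("Q", 1:4)))
  if (any(tab < 2))
    stop("analysis error: quadrant(s) with fewer than 2 positions: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  m$quadrant <- factor(m$quadrant, levels = paste0("Q", 1:4))
  group_means <- tapply(m$conservation, m$quadrant, mean)
  fit <- stats::aov(conservation ~ quadrant, data = m)
  sm <- summary(fit)[[1]]
  # Constant conservation: no between-group signal, report F = 0 rather
  # than the 0/0 form.
  if (sm[["Sum Sq"]][1] < 1e-12) {
    sm[["F value"]][1] <- 0
    sm[["Pr(>F)"]][1] <- 1
  }
  tk <- stats::TukeyHSD(fit)$quadrant
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(data = m, medians = c(npc_0h = med_x, npc_48h = med_y),
       group_means = group_means,
       anova = list(F = sm[["F value"]][1],
                    df = c(sm[["Df"]][1], sm[["Df"]][2]),
                    p = sm[["Pr(>F)"]][1]),
       tukey = tukey)
}

#' Two-way ANOVA of conservation on the two median-split classes
#'
#' Tests the interdependence of the two screened functions on the
#' evolutionary conservation score: main effects of the inhibition class
#' (0 h npc above/below median) and the stability class (48 h npc
#' above/below median) and their interaction, with type-II sums of squares
#' (the median splits are unbalanced in general).
#'
#' @param inhibition_class,stability_class Two-level factors or logicals
#'   per position.
#' @param conservation Numeric conservation scores per position.
#' @return List with one element per term (\code{inhibition},
#'   \code{stability}, \code{interaction}), each carrying \code{F},
#'   \code{df} (numerator, denominator) and \code{p}, plus
#'   \code{cell_means}.
#' @export
two_way_anova <- function(inhibition_class, stability_class, conservation) {
  a <- droplevels(as.factor(inhibition_class))
  b <- droplevels(as.factor(stability_class))
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("design error: both factors must vary")
  if (nlevels(interaction(a, b, drop = TRUE)) < 4)
    stop("design error: factors are confounded (empty cells)")
  dat <- data.frame(y = conservation, A = a, B = b)
  fit <- stats::lm(y ~ A * B, data = dat)
  an <- car::Anova(fit, type = 2)
  df_res <- an["Residuals", "Df"]
  term <- function(name) list(F = an[name, "F value"],
                              df = c(an[name, "Df"], df_res),
                              p = an[name, "Pr(>F)"])
  list(inhibition = term("A"), stability = term("B"),
       interaction = term("A:B"),
       cell_means = tapply(dat$y, list(dat$A, dat$B), mean))
}
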