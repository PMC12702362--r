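# Shared fixtures: small synthetic screens built in code, cached per run.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 11, ...) {
  args <- list(L = 60L, depth = 2e5, replicates = 3L, dispersion = 0.05,
               planted_regions = data.frame(start = c(15L, 40L),
                                            end = c(25L, 50L)),
               spike_ins = data.frame(variant = character(0),
                                      frequency = numeric(0)),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

small_screen <- function() {
  if (is.null(.fixtures$small)) {
    scr <- simulate_screen(small_config())
    s0 <- score_contrast(scr$counts, scr$samples, c("sel0h", "input"))
    s48 <- score_contrast(scr$counts, scr$samples, c("sel48h", "input"))
    .fixtures$small <- list(screen = scr, s0 = s0, s48 = s48,
                            refined = refine_functional_stability(s0, s48))
  }
  .fixtures$small
}

# Default-condition screen (full library size) scored on both contrasts.
default_screen <- function() {
  if (is.null(.fixtures$default)) {
    scr <- simulate_screen(sim_config(seed = 101))
    s0 <- score_contrast(scr$counts, scr$samples, c("sel0h", "input"))
    s48 <- score_contrast(scr$counts, scr$samples, c("sel48h", "input"))
    .fixtures$default <- list(screen = scr, s0 = s0, s48 = s48,
                              refined = refine_functional_stability(s0, s48))
  }
  .fixtures$default
}

# Match score rows back to ground-truth rows; returns truth rows aligned
# to the score table.
truth_for <- function(scores, truth) {
  tv <- truth$variants
  tv[match(paste0(scores$wt_aa, scores$position, scores$alt_aa),
           paste0(tv$wt_aa, tv$position, tv$alt_aa)), ]
}

# Independent brute-force Benjamini-Hochberg adjustment.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
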