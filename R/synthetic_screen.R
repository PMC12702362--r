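#' Configuration for a synthetic two-timepoint selection screen
#'
#' Builds and validates the configuration object that drives the synthetic
#' screen generator. Defaults emulate a site-saturation substitution library
#' over a 379-residue serpin (19 substitutions per site, 7201 candidate
#' variants, ~96\% present), phage-display selection for protease inhibition
#' before (0 h) and after (48 h) incubation at 37 degrees C, a wild-type
#' latency half-life of 1-2 h, and sequencing depth of 2e6 reads per sample
#' with mild negative-binomial overdispersion.
#'
#' @param L Protein length (number of mutagenized positions).
#' @param missing_fraction Fraction of the 19*L candidate substitutions
#'   absent from the library. The default leaves 6879 of 7201 present.
#' @param depth Sequencing reads per sample.
#' @param replicates Replicate libraries per condition.
#' @param dispersion Negative-binomial overdispersion of read counts
#'   (variance = mu + dispersion * mu^2); 0 gives multinomial sampling.
#' @param incubation_times Hours of 37 degree incubation before each
#'   selection; one selected condition per value (labelled "sel<t>h").
#' @param spike_ins data.frame with columns \code{variant} (one- or
#'   three-letter notation) and \code{frequency}: variants over-represented
#'   in the input library, e.g. cloning artifacts.
#' @param seed Integer seed; every stochastic step of the generator draws
#'   from one generator seeded with this value.
#' @param wt_half_life_range Uniform range (hours) for the latency
#'   half-life of wild-type-like variants.
#' @param stabilized_half_life_multiplier Multiplier applied to the
#'   half-life of functionally stabilized variants (> 1).
#' @param background_capture Probability floor for capture in the selection
#'   step, modelling nonspecific binding/carry-over in the
#'   immunoprecipitation; keeps fully decayed variants at a finite,
#'   strongly depleted frequency rather than absent.
#' @param misfolded_background_multiplier Multiplier on the background
#'   capture of nonfunctional (misfolded) variants: misfolded protein
#'   exposes hydrophobic surface and adsorbs nonspecifically to beads and
#'   antibody more than natively folded protein, so the background floor
#'   is class-dependent.
#' @param functional_activity_range Uniform range of inhibitory activity
#'   \code{a} for functional variants.
#' @param nonfunctional_activity_floor Upper bound on \code{a} for
#'   nonfunctional variants (drawn strictly below this floor, near 0).
#' @param include_nonfunctional If FALSE every variant is functional
#'   (used for null screens).
#' @param tol0_beta Two shape parameters of the Beta distribution from
#'   which each position's inhibition tolerance \code{tol0} (fraction of
#'   functional substitutions) is drawn.
#' @param region_tol48_range Uniform range of the per-position
#'   stabilization tolerance \code{tol48} inside planted stabilizing
#'   regions; positions outside regions have \code{tol48 = 0}.
#' @param planted_regions data.frame with columns \code{start}, \code{end}
#'   (1-based inclusive): intervals designated functionally stabilizing.
#'   NULL (the default) uses the canonical five-region layout clipped to
#'   the protein length.
#' @param input_jitter_sd Log-normal sd of the deviation from equal
#'   representation in the input library.
#' @param conservation_alpha,conservation_beta,conservation_noise_sd
#'   Parameters of the conservation-score model
#'   \code{score = alpha * tol0 - beta * tol48 + N(0, noise_sd)} (higher
#'   score = more evolutionary lability).
#' @param vep_noise_sd Gaussian noise sd of the synthetic variant-effect
#'   predictor score.
#' @param ddg_noise_sd Gaussian noise sd of the synthetic ddG tables
#'   (kcal/mol).
#' @param misfold_penalty ddG increment (kcal/mol) added to nonfunctional
#'   (misfolded) variants in both conformations.
#' @param ddg_baseline_active,ddg_baseline_latent Baseline ddG (kcal/mol)
#'   in the active and latent conformations.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(L = 379L,
                       missing_fraction = 0.0448,
                       depth = 2e6,
                       replicates = 3L,
                       dispersion = 0.05,
                       incubation_times = c(0, 48),
                       spike_ins = data.frame(
                         variant = c("I91L", "E242T"),
                         frequency = c(0.026, 0.014),
                         stringsAsFactors = FALSE),
                       seed = 1L,
                       wt_half_life_range = c(1, 2),
                       stabilized_half_life_multiplier = 20,
                       background_capture = 1e-3,
                       misfolded_background_multiplier = 3,
                       functional_activity_range = c(0.3, 1),
                       nonfunctional_activity_floor = 0.02,
                       include_nonfunctional = TRUE,
                       tol0_beta = c(2, 2),
                       region_tol48_range = c(0.6, 0.95),
                       planted_regions = NULL,
                       input_jitter_sd = 0.1,
                       conservation_alpha = 2,
                       conservation_beta = 0.75,
                       conservation_noise_sd = 0.25,
                       vep_noise_sd = 0.1,
                       ddg_noise_sd = 0.8,
                       misfold_penalty = 2.5,
                       ddg_baseline_active = 0.5,
                       ddg_baseline_latent = 1.0) {
  if (is.null(planted_regions)) {
    planted_regions <- data.frame(
      start = c(40L, 72L, 158L, 216L, 320L),
      end   = c(45L, 93L, 178L, 237L, 347L))
    planted_regions$end <- pmin(planted_regions$end, as.integer(L))
    planted_regions <- planted_regions[planted_regions$start <= L, ,
                                       drop = FALSE]
  }
  cfg <- list(L = as.integer(L), missing_fraction = missing_fraction,
              depth = depth, replicates = as.integer(replicates),
              dispersion = dispersion, incubation_times = incubation_times,
              spike_ins = spike_ins, seed = as.integer(seed),
              wt_half_life_range = wt_half_life_range,
              stabilized_half_life_multiplier = stabilized_half_life_multiplier,
              background_capture = background_capture,
              misfolded_background_multiplier = misfolded_background_multiplier,
              functional_activity_range = functional_activity_range,
              nonfunctional_activity_floor = nonfunctional_activity_floor,
              include_nonfunctional = isTRUE(include_nonfunctional),
              tol0_beta = tol0_beta,
              region_tol48_range = region_tol48_range,
              planted_regions = planted_regions,
              input_jitter_sd = input_jitter_sd,
              conservation_alpha = conservation_alpha,
              conservation_beta = conservation_beta,
              conservation_noise_sd = conservation_noise_sd,
              vep_noise_sd = vep_noise_sd,
              ddg_noise_sd = ddg_noise_sd,
              misfold_penalty = misfold_penalty,
              ddg_baseline_active = ddg_baseline_active,
              ddg_baseline_latent = ddg_baseline_latent)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$L < 1L)
    stop("configuration error: L must be >= 1")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction > 1)
    stop("configuration error: missing_fraction must lie in [0, 1]")
  if (cfg$depth <= 0)
    stop("configuration error: depth must be > 0")
  if (cfg$replicates < 1L)
    stop("configuration error: replicates must be >= 1")
  if (cfg$dispersion < 0)
    stop("configuration error: dispersion must be >= 0")
  if (any(cfg$incubation_times < 0))
    stop("configuration error: incubation times must be >= 0")
  if (nrow(cfg$spike_ins) > 0) {
    if (any(cfg$spike_ins$frequency < 0) || any(cfg$spike_ins$frequency > 1) ||
        sum(cfg$spike_ins$frequency) >= 1)
      stop("configuration error: spike-in frequencies must lie in [0, 1] and sum to < 1")
  }
  if (cfg$stabilized_half_life_multiplier < 1)
    stop("configuration error: stabilized_half_life_multiplier must be >= 1")
  if (any(cfg$wt_half_life_range <= 0) ||
      diff(cfg$wt_half_life_range) < 0)
    stop("configuration error: wt_half_life_range must be a positive (low, high) pair")
  if (nrow(cfg$planted_regions) > 0) {
    pr <- cfg$planted_regions
    if (any(pr$start < 1L) || any(pr$end > cfg$L) || any(pr$start > pr$end))
      stop("configuration error: planted regions must satisfy 1 <= start <= end <= L")
  }
  if (cfg$background_capture < 0 || cfg$background_capture >= 1)
    stop("configuration error: background_capture must lie in [0, 1)")
  if (cfg$misfolded_background_multiplier < 1)
    stop("configuration error: misfolded_background_multiplier must be >= 1")
  invisible(TRUE)
}

#' Generate ground-truth variant properties for a synthetic screen
#'
#' Enumerates all 19*L candidate substitutions over a (seeded, random)
#' wild-type sequence, marks a random subset as present in the library,
#' and assigns each variant an inhibitory activity \code{a} and a latency
#' half-life \code{h}. Per-position tolerances control the fraction of
#' functional substitutions (\code{tol0}) and, inside planted regions, the
#' fraction of functionally stabilizing substitutions (\code{tol48}).
#' Stabilized variants have their half-life multiplied by
#' \code{stabilized_half_life_multiplier}.
#'
#' @param config A \code{\link{sim_config}} object.
#' @return An object of class \code{ground_truth}: a list with elements
#'   \code{variants} (one row per candidate substitution: position, wt_aa,
#'   alt_aa, present, functional, stabilized, activity, half_life),
#'   \code{positions} (position, tol0, tol48, in_region),
#'   \code{planted_regions}, \code{wt_seq}, and \code{config}.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$L

  # Wild-type sequence: random draw, with spike-in wild-type residues pinned
  # so the default I91L / E242T artifacts are well defined.
  wt_seq <- sample(AA20, L, replace = TRUE)
  spikes <- NULL
  if (nrow(config$spike_ins) > 0) {
    spikes <- cbind(parse_variants(config$spike_ins$variant),
                    frequency = config$spike_ins$frequency)
    spikes <- spikes[spikes$position <= L, , drop = FALSE]
    wt_seq[spikes$position] <- spikes$wt_aa
  }

  # Candidate space: 19 substitutions per position.
  position <- rep(seq_len(L), each = 19L)
  wt_aa <- wt_seq[position]
  alt_aa <- unlist(lapply(seq_len(L), function(p) setdiff(AA20, wt_seq[p])),
                   use.names = FALSE)
  n_cand <- 19L * L

  # Per-position tolerances.
  in_region <- rep(FALSE, L)
  pr <- config$planted_regions
  if (nrow(pr) > 0)
    for (i in seq_len(nrow(pr)))
      in_region[pr$start[i]:pr$end[i]] <- TRUE
  tol0 <- stats::rbeta(L, config$tol0_beta[1], config$tol0_beta[2])
  tol48 <- ifelse(in_region,
                  stats::runif(L, config$region_tol48_range[1],
                               config$region_tol48_range[2]),
                  0)

  # Library membership.
  n_present <- ceiling((1 - config$missing_fraction) * n_cand)
  present <- rep(FALSE, n_cand)
  present[sample.int(n_cand, n_present)] <- TRUE

  # Per-variant functional class and activity.
  if (config$include_nonfunctional) {
    functional <- stats::runif(n_cand) < tol0[position]
  } else {
    functional <- rep(TRUE, n_cand)
  }
  activity <- numeric(n_cand)
  fr <- config$functional_activity_range
  activity[functional] <- stats::runif(sum(functional), fr[1], fr[2])
  activity[!functional] <- config$nonfunctional_activity_floor *
    stats::runif(sum(!functional), 0.1, 1)

  # Latency half-life; stabilization is planted inside regions only.
  half_life <- stats::runif(n_cand, config$wt_half_life_range[1],
                            config$wt_half_life_range[2])
  stabilized <- in_region[position] & (stats::runif(n_cand) < tol48[position])
  half_life[stabilized] <- half_life[stabilized] *
    config$stabilized_half_life_multiplier

  # Spike-in variants are always present; swap an absent spike in for a
  # random present variant so the present-set size stays exactly n_present.
  if (!is.null(spikes) && nrow(spikes) > 0) {
    key <- paste(position, alt_aa)
    idx <- match(paste(spikes$position, spikes$alt_aa), key)
    for (i in idx[!present[idx]]) {
      swap <- sample(setdiff(which(present), idx), 1)
      present[swap] <- FALSE
      present[i] <- TRUE
    }
  }

  variants <- data.frame(position = position, wt_aa = wt_aa, alt_aa = alt_aa,
                         present = present, functional = functional,
                         stabilized = stabilized, activity = activity,
                         half_life = half_life, stringsAsFactors = FALSE)
  positions <- data.frame(position = seq_len(L), tol0 = tol0, tol48 = tol48,
                          in_region = in_region)
  structure(list(variants = variants, positions = positions,
                 planted_regions = pr, wt_seq = wt_seq, config = config),
            class = "ground_truth")
}

#' Expected post-selection variant frequencies
#'
#' Deterministic selection model of the phage-display screen: a variant in
#' its active conformation is captured by the protease selection with
#' probability proportional to its inhibitory activity, and the fraction
#' still active after \code{time} hours of incubation decays exponentially
#' with the variant's latency half-life. The per-variant capture
#' probability is \code{p = activity * 2^(-time / half_life) + background},
#' and selected frequencies are the renormalized product of input
#' frequency and capture probability.
#'
#' @param input_freqs Numeric vector of input frequencies (sums to 1).
#' @param activity Per-variant inhibitory activity in [0, 1].
#' @param half_life Per-variant latency half-life in hours (> 0).
#' @param time Incubation time in hours (>= 0).
#' @param background Nonspecific capture floor (default 0); scalar or
#'   per-variant vector.
#' @return Numeric vector of post-selection frequencies summing to 1.
#' @export
simulate_selection <- function(input_freqs, activity, half_life, time,
                               background = 0) {
  if (abs(sum(input_freqs) - 1) > 1e-6)
    stop("input frequencies must sum to 1")
  if (time < 0) stop("incubation time must be >= 0")
  if (any(half_life <= 0)) stop("half-lives must be > 0")
  p <- activity * 2^(-time / half_life) + background
  w <- input_freqs * p
  tot <- sum(w)
  if (tot == 0)
    stop("degenerate selection: every capture probability is zero")
  w / tot
}

#' Sample sequencing read counts for one condition
#'
#' Draws replicate read-count columns at the given frequencies. With
#' \code{dispersion = 0} each replicate is a multinomial draw of
#' \code{depth} reads; with \code{dispersion > 0} counts are independent
#' negative-binomial draws with mean \code{depth * f} and variance
#' \code{mu + dispersion * mu^2}.
#'
#' @param freqs Frequencies summing to 1.
#' @param depth Reads per replicate.
#' @param replicates Number of replicate columns.
#' @param dispersion Negative-binomial overdispersion (>= 0).
#' @param condition Condition label used to name columns
#'   ("<condition>_<replicate>").
#' @return Integer matrix, one row per variant, one column per replicate.
#' @export
sample_read_counts <- function(freqs, depth, replicates = 3L,
                               dispersion = 0.05, condition = "sample") {
  if (dispersion < 0) stop("configuration error: dispersion must be >= 0")
  if (depth <= 0) stop("configuration error: depth must be > 0")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  n <- length(freqs)
  counts <- matrix(0L, nrow = n, ncol = replicates)
  for (j in seq_len(replicates)) {
    if (dispersion == 0) {
      counts[, j] <- as.integer(stats::rmultinom(1, size = depth, prob = freqs))
    } else {
      counts[, j] <- as.integer(stats::rnbinom(n, mu = depth * freqs,
                                               size = 1 / dispersion))
    }
  }
  colnames(counts) <- paste(condition, seq_len(replicates), sep = "_")
  counts
}

# Input library frequencies: near-equal representation of present variants
# with log-normal jitter, then spike-in frequencies imposed.
input_frequencies <- function(truth) {
  cfg <- truth$config
  v <- truth$variants
  f <- numeric(nrow(v))
  f[v$present] <- exp(stats::rnorm(sum(v$present), 0, cfg$input_jitter_sd))
  f <- f / sum(f)
  if (nrow(cfg$spike_ins) > 0) {
    spikes <- cbind(parse_variants(cfg$spike_ins$variant),
                    frequency = cfg$spike_ins$frequency)
    spikes <- spikes[spikes$position <= cfg$L, , drop = FALSE]
    if (nrow(spikes) > 0) {
      idx <- match(paste(spikes$position, spikes$alt_aa),
                   paste(v$position, v$alt_aa))
      f[idx] <- 0
      f <- f / sum(f) * (1 - sum(spikes$frequency))
      f[idx] <- spikes$frequency
    }
  }
  f
}

#' Generate synthetic predictor tables correlated with function
#'
#' Emulates variant-effect predictor (VEP) and protein-stability predictor
#' (ddG) tables for every candidate variant. The VEP score is a monotone
#' decreasing function of inhibitory activity plus Gaussian noise, clipped
#' to [0, 1] (higher = more pathogenic). The ddG tables carry a constant
#' baseline per conformation plus a misfolding penalty for nonfunctional
#' variants plus noise; by construction they do not depend on the latency
#' half-life, mirroring predictors that see folding stability but not
#' transition kinetics.
#'
#' @param truth A \code{ground_truth} object.
#' @param vep_noise_sd,ddg_noise_sd Noise levels; default from the
#'   generating config.
#' @return data.frame with columns position, wt_aa, alt_aa, vep_score,
#'   ddg_active, ddg_latent.
#' @export
generate_predictor_tables <- function(truth,
                                      vep_noise_sd = truth$config$vep_noise_sd,
                                      ddg_noise_sd = truth$config$ddg_noise_sd) {
  cfg <- truth$config
  v <- truth$variants
  n <- nrow(v)
  misfolded <- v$activity <= cfg$nonfunctional_activity_floor
  vep <- 0.85 - 0.75 * v$activity + stats::rnorm(n, 0, vep_noise_sd)
  vep <- pmin(1, pmax(0, vep))
  ddg_active <- cfg$ddg_baseline_active + cfg$misfold_penalty * misfolded +
    stats::rnorm(n, 0, ddg_noise_sd)
  ddg_latent <- cfg$ddg_baseline_latent + cfg$misfold_penalty * misfolded +
    stats::rnorm(n, 0, ddg_noise_sd)
  data.frame(position = v$position, wt_aa = v$wt_aa, alt_aa = v$alt_aa,
             vep_score = vep, ddg_active = ddg_active,
             ddg_latent = ddg_latent, stringsAsFactors = FALSE)
}

#' Generate per-position conservation scores
#'
#' Conservation scores emulate per-residue evolutionary variability from an
#' orthologue alignment (higher score = more lability, less conservation).
#' The planted model is \code{score = alpha * tol0 - beta * tol48 + noise}:
#' positions tolerant of substitution with respect to inhibition are more
#' labile, while positions harbouring functionally stabilizing
#' substitutions are under additional purifying selection against slowed
#' latency and hence less labile.
#'
#' @param truth A \code{ground_truth} object.
#' @param alpha,beta Nonnegative dependence coefficients.
#' @param noise_sd Gaussian noise sd.
#' @return data.frame with columns position, conservation.
#' @export
generate_conservation_scores <- function(truth,
                                         alpha = truth$config$conservation_alpha,
                                         beta = truth$config$conservation_beta,
                                         noise_sd = truth$config$conservation_noise_sd) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  p <- truth$positions
  score <- alpha * p$tol0 - beta * p$tol48 +
    stats::rnorm(nrow(p), 0, noise_sd)
  data.frame(position = p$position, conservation = score)
}

#' Simulate a complete two-timepoint selection screen
#'
#' Runs the whole generator under one seed: ground truth, input library
#' frequencies, expected post-selection frequencies at each incubation
#' time, replicate read counts for the input and every selected condition,
#' predictor tables, and conservation scores. Stochastic steps draw from a
#' single generator seeded with \code{config$seed}, in that order.
#'
#' @param config A \code{\link{sim_config}} object.
#' @return An object of class \code{serpin_screen}: list with elements
#'   \code{truth}, \code{counts} (integer matrix, variants x samples, row
#'   names in one-letter variant notation; only library-present variants),
#'   \code{samples} (sample, condition, replicate), \code{input_freqs},
#'   \code{predictors}, \code{conservation}, \code{config}.
#' @export
simulate_screen <- function(config) {
  truth <- generate_ground_truth(config)
  v <- truth$variants
  f_in <- input_frequencies(truth)

  present <- v$present
  conds <- c("input", paste0("sel", config$incubation_times, "h"))
  blocks <- vector("list", length(conds))
  blocks[[1]] <- sample_read_counts(f_in[present] / sum(f_in[present]),
                                    config$depth, config$replicates,
                                    config$dispersion, "input")
  bg <- config$background_capture *
    ifelse(v$functional, 1, config$misfolded_background_multiplier)
  for (k in seq_along(config$incubation_times)) {
    f_sel <- simulate_selection(f_in, v$activity, v$half_life,
                                config$incubation_times[k],
                                background = bg)
    blocks[[k + 1]] <- sample_read_counts(f_sel[present] / sum(f_sel[present]),
                                          config$depth, config$replicates,
                                          config$dispersion, conds[k + 1])
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- variant_key(v[present, ])
  samples <- data.frame(sample = colnames(counts),
                        condition = rep(conds, each = config$replicates),
                        replicate = rep(seq_len(config$replicates),
                                        times = length(conds)),
                        stringsAsFactors = FALSE)
  predictors <- generate_predictor_tables(truth)
  conservation <- generate_conservation_scores(truth)
  structure(list(truth = truth, counts = counts, samples = samples,
                 input_freqs = f_in, predictors = predictors,
                 conservation = conservation, config = config),
            class = "serpin_screen")
}
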