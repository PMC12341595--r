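# Synthetic-data generators with known ground truth. They emulate the assay
# design (acceptor / no-acceptor wells, mock and WT constructs on every
# plate, triplicate signals, independent experiments) with multiplicative
# log-normal noise on every band/well, chosen because all downstream
# statistics are ratios; per-experiment scale jitter is harmless by
# construction and the tests verify exactly that.
#
# Generative model per construct x experiment x condition: a well-set total
# signal T ~ LogNormal(log(scale), jitter) is split into medium = T * f * eps
# and lysate = T * (1 - f) * eps' with per-well noise eps ~ LogNormal(0,
# sigma). The acceptor-well efflux fraction is f = leakage + nonspecific +
# (activity / 100) * (wt_efflux - leakage - nonspecific); no-acceptor wells
# use f = leakage; mock acceptor wells use f = leakage + nonspecific. Under
# this model the pipeline's (construct - mock) / (WT - mock) estimator
# returns the true activity exactly at zero noise.

#' Specification for the synthetic-data generators
#'
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @param n_experiments Independent experiments (4 for efflux/surface, 5 for
#'   rescue in the emulated design).
#' @param activities Named numeric vector: true relative activity (percent of
#'   WT) per variant construct.
#' @param wt_efflux True WT acceptor-well efflux fraction.
#' @param leakage No-acceptor (HDL-nonspecific) efflux fraction.
#' @param nonspecific Mock (ABCA1-nonspecific) efflux above leakage.
#' @param scale Well-set total signal scale, arbitrary fluorescence units.
#' @param sigma Per-well multiplicative log-normal noise SD (log scale).
#' @param jitter Per-experiment log-normal scale jitter SD.
#' @param surface_truth Optional data frame `construct_id`, `raw_pct`,
#'   `corr_pct`: true surface levels as percent of WT.
#' @param rescue_profiles Optional named character vector per variant, each
#'   one of `"rescuable"`, `"atpase_deficient"`, `"unaffected"`.
#' @param rescue_gain Percentage-point efflux gain under 4-PBA for rescuable
#'   variants.
#' @param surface_gain_factor Multiplicative cell-surface gain under 4-PBA
#'   (applies to every construct; 4-PBA increases surface protein broadly).
#' @return A list of class `"generator_spec"`.
#' @export
generator_spec <- function(seed = 1L,
                           n_experiments = 4L,
                           activities = c(var_lof = 20, var_mid = 60, var_norm = 100),
                           wt_efflux = 0.30,
                           leakage = 0.05,
                           nonspecific = 0.02,
                           scale = 1000,
                           sigma = 0.10,
                           jitter = 0.15,
                           surface_truth = NULL,
                           rescue_profiles = NULL,
                           rescue_gain = 30,
                           surface_gain_factor = 1.8) {
  stopifnot(wt_efflux > 0, wt_efflux <= 1, leakage >= 0, nonspecific >= 0,
            wt_efflux > leakage + nonspecific,
            sigma >= 0, jitter >= 0, scale > 0, n_experiments >= 1,
            !is.null(names(activities)), all(nzchar(names(activities))))
  if (!is.null(rescue_profiles))
    stopifnot(all(rescue_profiles %in% c("rescuable", "atpase_deficient", "unaffected")))
  structure(as.list(environment()), class = "generator_spec")
}

# truth-level acceptor-well efflux fraction for a given activity (% of WT)
acceptor_fraction <- function(activity, spec) {
  f <- spec$leakage + spec$nonspecific +
    (activity / 100) * (spec$wt_efflux - spec$leakage - spec$nonspecific)
  min(max(f, 0), 1)
}

lnoise <- function(n, sigma) if (sigma > 0) stats::rlnorm(n, 0, sigma) else rep(1, n)

#' Generate a synthetic plate table
#'
#' @param spec A [generator_spec()].
#' @param treatment Treatment label for the generated arm.
#' @param activities Optional override of `spec$activities` (used internally
#'   for the 4-PBA arm).
#' @param .reseed Seed the RNG from `spec$seed` before drawing (default);
#'   internal callers that manage the seed themselves pass `FALSE`.
#' @return Long plate table as consumed by [run_efflux_pipeline()]: one row
#'   per construct x experiment x condition x well type with `rep1..rep3`.
#' @export
generate_plates <- function(spec, treatment = "mock", activities = NULL,
                            .reseed = TRUE) {
  stopifnot(inherits(spec, "generator_spec"))
  if (.reseed) set.seed(spec$seed)
  if (is.null(activities)) activities <- spec$activities
  constructs <- c(names(activities), "WT", "mock")
  act <- c(activities, WT = 100, mock = NA)
  rows <- list(); k <- 0L
  for (e in seq_len(spec$n_experiments)) {
    exp_id <- sprintf("E%d", e)
    for (cid in constructs) {
      for (cond in c("acceptor", "no_acceptor")) {
        f <- if (cond == "no_acceptor") spec$leakage
             else if (cid == "mock") spec$leakage + spec$nonspecific
             else acceptor_fraction(act[[cid]], spec)
        total <- spec$scale * lnoise(1, spec$jitter)
        med <- total * f * lnoise(3, spec$sigma)
        lys <- total * (1 - f) * lnoise(3, spec$sigma)
        k <- k + 1L
        rows[[k]] <- data.frame(
          construct_id = cid, experiment_id = exp_id, condition = cond,
          treatment = treatment,
          well_type = c("medium", "lysate"),
          rep1 = c(med[1], lys[1]), rep2 = c(med[2], lys[2]),
          rep3 = c(med[3], lys[3]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic plates for both 4-PBA rescue arms
#'
#' Vehicle-arm activities are `spec$activities`; under 4-PBA, `"rescuable"`
#' variants gain `spec$rescue_gain` percentage points while
#' `"atpase_deficient"` and `"unaffected"` variants are unchanged.
#'
#' @param spec A [generator_spec()] with `rescue_profiles` set for every
#'   variant in `activities`.
#' @return A plate table covering treatments `"mock"` and `"4pba"`.
#' @export
generate_rescue_plates <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), !is.null(spec$rescue_profiles))
  prof <- spec$rescue_profiles[names(spec$activities)]
  stopifnot(!any(is.na(prof)))
  act_pba <- spec$activities + ifelse(prof == "rescuable", spec$rescue_gain, 0)
  set.seed(spec$seed)
  rbind(generate_plates(spec, treatment = "mock", .reseed = FALSE),
        generate_plates(spec, treatment = "4pba", activities = act_pba,
                        .reseed = FALSE))
}

#' Generate a synthetic densitometry table
#'
#' Band intensities are drawn around the `surface_truth` levels with
#' multiplicative log-normal noise; the beta-actin loading band varies around
#' a constant. Under 4-PBA (when requested) every construct's surface and
#' total bands are multiplied by `spec$surface_gain_factor` except
#' `"unaffected"` rescue profiles.
#'
#' @param spec A [generator_spec()] with `surface_truth` set.
#' @param treatments Treatment arms to generate (default `"mock"` only).
#' @param .reseed Seed the RNG from `spec$seed` before drawing (default).
#' @return Band table as consumed by [surface_levels()]: `construct_id`,
#'   `experiment_id`, `treatment`, `surface`, `total`, `actin`.
#' @export
generate_bands <- function(spec, treatments = "mock", .reseed = TRUE) {
  stopifnot(inherits(spec, "generator_spec"), !is.null(spec$surface_truth))
  if (.reseed) set.seed(spec$seed)
  tr <- spec$surface_truth
  stopifnot(all(c("construct_id", "raw_pct", "corr_pct") %in% names(tr)))
  s0 <- 100; t0 <- 100; a0 <- 50  # WT band levels, arbitrary units
  rows <- list(); k <- 0L
  for (trt in treatments) {
    for (e in seq_len(spec$n_experiments)) {
      exp_id <- sprintf("E%d", e)
      gain_wt <- if (trt == "4pba") spec$surface_gain_factor else 1
      k <- k + 1L
      rows[[k]] <- data.frame(construct_id = "WT", experiment_id = exp_id,
                              treatment = trt,
                              surface = s0 * gain_wt * lnoise(1, spec$sigma),
                              total = t0 * gain_wt * lnoise(1, spec$sigma),
                              actin = a0 * lnoise(1, spec$sigma),
                              stringsAsFactors = FALSE)
      for (i in seq_len(nrow(tr))) {
        cid <- tr$construct_id[i]
        gain <- 1
        if (trt == "4pba") {
          prof <- if (!is.null(spec$rescue_profiles) && cid %in% names(spec$rescue_profiles))
            spec$rescue_profiles[[cid]] else "rescuable"
          gain <- if (prof == "unaffected") 1 else spec$surface_gain_factor
        }
        surf <- s0 * tr$raw_pct[i] / 100 * gain
        tot <- t0 * (tr$raw_pct[i] / tr$corr_pct[i]) * gain
        k <- k + 1L
        rows[[k]] <- data.frame(construct_id = cid, experiment_id = exp_id,
                                treatment = trt,
                                surface = surf * lnoise(1, spec$sigma),
                                total = tot * lnoise(1, spec$sigma),
                                actin = a0 * lnoise(1, spec$sigma),
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic variant annotation table
#'
#' Produces one variant per allele-frequency tier (BA1 / BS1 / PM2 / none)
#' crossed with the PP4 phenotype tiers (supporting / moderate / strong via
#' HDL-C, strong via Tangier, none), with valid HGVS p. names at intracellular
#' ABCA1 positions.
#'
#' @param spec A [generator_spec()] (only the seed is used).
#' @param config A [calibration_config()] supplying the tier cutoffs.
#' @return Data frame with columns `variant_p`, `variant_c`, `faf`, `hdl_c`,
#'   `tangier`, `criteria` plus ground-truth columns `true_freq_criterion`
#'   and `true_pp4`.
#' @export
generate_variant_table <- function(spec = generator_spec(),
                                   config = calibration_config()) {
  freq_tiers <- list(BA1 = config$freq_ba1 * 2, BS1 = config$freq_bs1 * 1.2,
                     PM2 = config$freq_pm2 / 2, none = config$freq_pm2 * 5)
  pheno_tiers <- list(
    PP4 = list(hdl = config$pp4_supporting_hdl - 0.05, tangier = FALSE),
    PP4_moderate = list(hdl = config$pp4_moderate_hdl - 0.05, tangier = FALSE),
    PP4_strong = list(hdl = config$pp4_strong_hdl - 0.05, tangier = FALSE),
    PP4_strong_tangier = list(hdl = NA_real_, tangier = TRUE),
    none = list(hdl = NA_real_, tangier = FALSE))
  aas <- setdiff(AA_1, "X")
  positions <- seq(905, by = 7, length.out = length(freq_tiers) * length(pheno_tiers))
  rows <- list(); k <- 0L
  for (fi in seq_along(freq_tiers)) {
    for (pi in seq_along(pheno_tiers)) {
      k <- k + 1L
      ref <- aas[(k - 1L) %% 20L + 1L]
      alt <- aas[k %% 20L + 1L]
      if (alt == ref) alt <- aas[(k + 1L) %% 20L + 1L]
      ph <- pheno_tiers[[pi]]
      rows[[k]] <- data.frame(
        variant_p = sprintf("p.%s%d%s", ref, positions[k], alt),
        variant_c = ".", faf = freq_tiers[[fi]], hdl_c = ph$hdl,
        tangier = ph$tangier, criteria = ".",
        true_freq_criterion = names(freq_tiers)[fi],
        true_pp4 = sub("_tangier$", "", names(pheno_tiers)[pi]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a protein sequence with two homologous domains
#'
#' Builds a random domain, duplicates it with independent per-residue
#' divergence, and embeds both copies between linkers, returning the planted
#' ground truth (which positions stayed conserved and the exact position
#' correspondence) so alignment-based recovery can be asserted.
#'
#' @param domain_length Length of each domain copy.
#' @param divergence Per-residue probability of substitution in the second
#'   copy.
#' @param linker_length Length of the N-terminal, inter-domain and C-terminal
#'   linkers (poly-linker of low-complexity residues).
#' @param seed Optional integer seed (`NULL` leaves the RNG state alone).
#' @return A list with `sequence`, `nbd1_window`, `nbd2_window`,
#'   `pairs` (data frame `nbd1_pos`, `nbd2_pos`, `conserved`).
#' @export
generate_duplicated_domain_sequence <- function(domain_length = 80,
                                                divergence = 0.3,
                                                linker_length = 15,
                                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aas <- AA_1
  d1 <- sample(aas, domain_length, replace = TRUE)
  mutate <- stats::runif(domain_length) < divergence
  d2 <- d1
  for (i in which(mutate)) d2[i] <- sample(setdiff(aas, d1[i]), 1)
  linker <- rep("G", linker_length)
  seqv <- c(linker, d1, linker, d2, linker)
  w1 <- c(linker_length + 1L, linker_length + domain_length)
  w2 <- c(2L * linker_length + domain_length + 1L,
          2L * linker_length + 2L * domain_length)
  list(sequence = paste(seqv, collapse = ""),
       nbd1_window = w1, nbd2_window = w2,
       pairs = data.frame(nbd1_pos = w1[1]:w1[2], nbd2_pos = w2[1]:w2[2],
                          conserved = d1 == d2))
}
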