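#' @title Synthetic slide datasets with known ground truth
#' @description Generates complete spot-level datasets whose generative model
#'   deliberately matches the analysis model (Langmuir-like hybridization,
#'   first-order decay, Michaelis-Menten induced-fit modulation, lognormal
#'   multiplicative replicate noise, rare planted morphology/background spot
#'   failures), so that a zero-noise dataset is recovered exactly by the
#'   pipeline — the standard simulation-based-calibration posture. Defaults
#'   mirror the published study conditions: 6 sub-arrays per slide (one
#'   Calibration, one BufferOnly, four Ligand), two slides giving 8
#'   log-spaced dilutions from 0.124 uM to 10 mM, 5 replicate spots per ACE,
#'   1 h incubations, ~0.2% spot-failure rates, K_Fit = 200 uM for
#'   induced-fit-competent ("hot") designs and planted k*_off,max between
#'   0.3 and 1.0 1/h over a 0.05-0.25 1/h spontaneous k_off baseline
#'   (i.e. 6- to 10-fold ligand-induced rate increases at saturation).
#' @name simulate
NULL

#' Log-spaced dilution series
#'
#' @param low,high Endpoint concentrations, molar (both included exactly).
#' @param n Number of concentrations.
#' @return Increasing numeric vector with constant consecutive ratios.
#' @examples
#' dilution_series(0.124e-6, 10e-3, 8)
#' @export
dilution_series <- function(low, high, n) {
  if (!(low > 0) || !(high >= low) || n < 1) {
    stop_violation("need 0 < low <= high and n >= 1")
  }
  if (n == 1L) return(low)
  out <- exp(seq(log(low), log(high), length.out = n))
  out[1] <- low; out[n] <- high
  out
}

#' Build a simulation scenario
#'
#' Presets plant different ground truths on the 32-nt ATP-aptamer-like
#' construct ([atp_dna_construct()]):
#' * `atp_dna_like` — induced fit (`k*_max > 0`) exactly on 7- to 12-mer
#'   designs overlapping the planted ligand-contact site (consensus
#'   coordinates 4..12), scaled `0.3 + 0.7 * overlap fraction` 1/h with
#'   K_Fit = 200 uM; mismatched variants of hot windows get a 1.5x boost
#'   (capped at 1.2 1/h); k_off elevated for designs overlapping the
#'   terminal stem-forming regions.
#' * `cocaine_like` — the same heterogeneous, structure-dependent k_off and
#'   hybridization landscape but zero induced fit everywhere.
#' * `flat_null` — uniform k_off, zero induced fit.
#'
#' @param preset `"atp_dna_like"`, `"cocaine_like"` or `"flat_null"`.
#' @param seed Integer seed (also the default layout/simulation seed).
#' @param lengths Perfect-match ACE lengths (default 7:12).
#' @param mismatch_lengths ACE lengths for single-mismatch scans
#'   (default none).
#' @param noise_sigma Lognormal sdlog of replicate noise (default 0.10;
#'   0 gives a noiseless dataset).
#' @param failure_morphology,failure_background Per-spot planted failure
#'   probabilities (default 0.002 each).
#' @param phi Calibration handling-loss fraction (default 0.15).
#' @param concentrations Ligand dilution series, molar.
#' @param replicates Replicate spots per ACE per sub-array (default 5).
#' @return An `ace_scenario` list with `aptamer`, `designs`, `truth`
#'   (per-ACE `k_off`, `k_star_max`, `K_fit`, `hot`), hybridization, noise
#'   and failure parameters.
#' @export
make_scenario <- function(preset = c("atp_dna_like", "cocaine_like",
                                     "flat_null"),
                          seed = 1L, lengths = 7:12,
                          mismatch_lengths = integer(0),
                          noise_sigma = 0.10,
                          failure_morphology = 0.002,
                          failure_background = 0.002,
                          phi = 0.15,
                          concentrations = dilution_series(0.124e-6, 10e-3, 8),
                          replicates = 5L) {
  preset <- match.arg(preset)
  aptamer <- atp_dna_construct()
  designs <- enumerate_perfect_match(aptamer, min(lengths), max(lengths))
  designs <- designs[designs$length %in% lengths, , drop = FALSE]
  if (length(mismatch_lengths)) {
    designs <- rbind(designs,
                     enumerate_single_mismatch(aptamer, mismatch_lengths))
  }
  rownames(designs) <- NULL

  site <- c(4L, 12L)   # planted ligand-contact coordinates
  stems <- list(c(-5L, -1L), c(22L, 27L)) # planted stem-competing regions
  i0 <- coord_to_index(designs$start5, aptamer)
  cov_from <- index_to_coord(i0, aptamer)
  cov_to <- index_to_coord(i0 + designs$length - 1L, aptamer)
  overlap_len <- function(a, b) {
    ia <- coord_to_index(a[1], aptamer); ib <- coord_to_index(a[2], aptamer)
    pmax(0L, pmin(i0 + designs$length - 1L, ib) - pmax(i0, ia) + 1L)
  }
  site_ov <- overlap_len(site) / designs$length
  stem_ov <- pmax(overlap_len(stems[[1]]), overlap_len(stems[[2]])) /
    designs$length

  k_off <- switch(preset,
                  flat_null = rep(0.05, nrow(designs)),
                  0.05 + 0.20 * stem_ov)
  hot <- preset == "atp_dna_like" & designs$length >= 7L &
    designs$length <= 12L & site_ov > 0
  k_star_max <- ifelse(hot, 0.3 + 0.7 * site_ov, 0)
  boost <- hot & !is.na(designs$mismatch_pos)
  k_star_max[boost] <- pmin(1.5 * k_star_max[boost], 1.2)
  K_fit <- ifelse(hot, 200e-6, NA_real_)

  truth <- data.frame(ace_id = designs$ace_id, k_off = k_off,
                      k_star_max = k_star_max, K_fit = K_fit, hot = hot,
                      stringsAsFactors = FALSE)
  structure(list(
    preset = preset, seed = as.integer(seed), aptamer = aptamer,
    designs = designs, truth = truth,
    hyb = list(F_max = 5e4, dG0 = -10, slope = 2,
               cond = thermo_conditions(23, 0.3, 0.005)),
    noise = list(sigma = noise_sigma, background_mean = 50,
                 background_sd = 10, pixel_cv = 0.08, pixel_cv_jitter = 0.01),
    failure_rates = list(morphology = failure_morphology,
                         background = failure_background),
    phi = phi, concentrations = concentrations,
    replicates = as.integer(replicates), delta_t = 1),
    class = "ace_scenario")
}

#' Default condition table for a scenario
#'
#' Each slide carries one Calibration, one BufferOnly and four Ligand
#' sub-arrays; the scenario's dilution series is dealt across slides in
#' order, so 8 concentrations occupy 2 slides (12 sub-arrays), as in a
#' two-slide dilution experiment.
#'
#' @param scenario An `ace_scenario`.
#' @param n_slides Number of slides (default: enough for all concentrations).
#' @param ligand_name Label for the ligand.
#' @return Condition data frame (see [read_condition_table()]).
#' @export
make_conditions <- function(scenario, n_slides = NULL, ligand_name = "ATP") {
  conc <- scenario$concentrations
  per_slide <- 4L
  if (is.null(n_slides)) n_slides <- ceiling(length(conc) / per_slide)
  if (length(conc) > n_slides * per_slide) {
    stop_violation("%d concentrations do not fit on %d slides (4 per slide)",
                   length(conc), n_slides)
  }
  rows <- lapply(seq_len(n_slides), function(s) {
    cc <- conc[seq((s - 1L) * per_slide + 1L, min(s * per_slide,
                                                  length(conc)))]
    k <- length(cc)
    data.frame(
      subarray_id = sprintf("s%d_sa%d", s, seq_len(2L + k)),
      slide_id = sprintf("slide%d", s),
      condition = c("Calibration", "BufferOnly", rep("Ligand", k)),
      ligand_name = c("", "", rep(ligand_name, k)),
      concentration = c(0, 0, cc),
      temperature = scenario$hyb$cond$temperature,
      delta_t = scenario$delta_t,
      buffer_label = "assay",
      stringsAsFactors = FALSE)
  })
  validate_conditions(do.call(rbind, rows))
}

#' Simulate a spot-level dataset
#'
#' Per spot: post-hybridization green signal
#' `F_hyb = F_max * plogis(-(dG - dG0)/slope) * eps` (Langmuir-like
#' occupancy in the duplex free energy, lognormal replicate noise `eps`),
#' and post-incubation signal
#' `F_post = F_hyb * (1 - phi) * exp(-k_total * delta_t) * eps'` with
#' `k_total = k_off + k*_max [L]/(K_fit + [L])` (0 on the Calibration
#' sub-array, `k_off` for BufferOnly). Pixel SDs encode a base CV; planted
#' morphology failures inflate the spot CV 10x and planted background
#' failures inflate the local background 10x, each at the configured rate,
#' on the post-hybridization green image. Fully deterministic given `seed`.
#'
#' @param scenario An `ace_scenario` from [make_scenario()].
#' @param conditions Condition table (default [make_conditions()]).
#' @param layout Optional [assign_layout()] result; default lays the
#'   scenario's designs out with its replicate count and seed.
#' @param seed Simulation seed (default: scenario seed).
#' @return A `slide_dataset` list: `spots`, `conditions`, `layout`,
#'   `truth`, `scenario`.
#' @export
simulate_slide <- function(scenario, conditions = make_conditions(scenario),
                           layout = NULL, seed = scenario$seed) {
  conditions <- validate_conditions(conditions)
  if (is.null(layout)) {
    layout <- assign_layout(scenario$designs, n_subarrays = 1L,
                            replicates = scenario$replicates,
                            seed = scenario$seed)
  }
  pos <- layout$positions[layout$positions$subarray_id ==
                            layout$positions$subarray_id[1], , drop = FALSE]
  if (!setequal(pos$ace_id, scenario$designs$ace_id)) {
    stop_violation("layout designs do not match scenario designs")
  }
  truth_k_off <- stats::setNames(scenario$truth$k_off, scenario$truth$ace_id)
  truth_kmax <- stats::setNames(scenario$truth$k_star_max,
                                scenario$truth$ace_id)
  truth_K <- stats::setNames(scenario$truth$K_fit, scenario$truth$ace_id)
  dg <- duplex_dG(scenario$designs, scenario$aptamer, scenario$hyb$cond)
  occ <- stats::plogis(-(dg - scenario$hyb$dG0) / scenario$hyb$slope)
  F_true <- stats::setNames(scenario$hyb$F_max * occ,
                            scenario$designs$ace_id)
  ns <- scenario$noise
  sig <- ns$sigma
  lnoise <- function(n) {
    if (sig == 0) rep(1, n) else stats::rlnorm(n, -sig^2 / 2, sig)
  }
  with_seed(seed, {
    spots <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(ci) {
      cd <- conditions[ci, ]
      k_tot <- switch(
        cd$condition,
        Calibration = rep(0, nrow(pos)),
        BufferOnly = truth_k_off[pos$ace_id],
        Ligand = {
          km <- truth_kmax[pos$ace_id]; K <- truth_K[pos$ace_id]
          mm <- ifelse(km > 0, km * cd$concentration /
                         (K + cd$concentration), 0)
          truth_k_off[pos$ace_id] + mm
        })
      n <- nrow(pos)
      f_hyb <- F_true[pos$ace_id] * lnoise(n)
      f_post <- f_hyb * (1 - scenario$phi) * exp(-k_tot * cd$delta_t) *
        lnoise(n)
      # base pixel-CV jitter and backgrounds are uniform, hence bounded
      # within sqrt(3) sd of their mean: healthy spots can never cross a
      # mean + 3 sd cutoff, so planted failures are unambiguous
      cv <- ns$pixel_cv *
        (1 + stats::runif(n, -1, 1) * sqrt(3) * ns$pixel_cv_jitter)
      bad_morph <- stats::runif(n) < scenario$failure_rates$morphology
      cv[bad_morph] <- cv[bad_morph] * 10
      bg <- pmax(ns$background_mean +
                   stats::runif(n, -1, 1) * sqrt(3) * ns$background_sd, 1)
      bad_bg <- stats::runif(n) < scenario$failure_rates$background
      bg[bad_bg] <- bg[bad_bg] * 10
      base <- data.frame(
        subarray_id = cd$subarray_id, slide_id = cd$slide_id,
        ace_id = pos$ace_id, replicate = pos$replicate,
        grid_row = pos$grid_row, grid_col = pos$grid_col,
        stringsAsFactors = FALSE)
      rbind(
        cbind(base, round = "post_hyb", channel = "green",
              median_signal = unname(f_hyb), pixel_sd = unname(cv * f_hyb),
              background_mean = bg, planted_morphology = bad_morph,
              planted_background = bad_bg, stringsAsFactors = FALSE),
        cbind(base, round = "post_incubation", channel = "green",
              median_signal = unname(f_post), pixel_sd = unname(cv * f_post),
              background_mean = bg, planted_morphology = FALSE,
              planted_background = FALSE, stringsAsFactors = FALSE))
    }))
    rownames(spots) <- NULL
    structure(list(spots = validate_spots(spots), conditions = conditions,
                   layout = layout, truth = scenario$truth,
                   scenario = scenario),
              class = "slide_dataset")
  })
}
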