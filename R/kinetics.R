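#' @title Calibrated fluorescence losses and dissociation rates
#' @description Between the post-hybridization and post-incubation images
#'   every DA loses fluorescence through handling (drying, washing,
#'   photobleaching) as well as through genuine duplex dissociation. The
#'   Calibration sub-array, which is imaged but never incubated, measures the
#'   handling component: per DA, condition fluorescence losses are divided by
#'   the Calibration loss (so the Calibration condition is 100% by
#'   construction), and the handling-corrected survival fraction is converted
#'   to a first-order dissociation rate over the incubation interval. The
#'   ligand-induced (induced-fit) rate is the excess of the ligand-condition
#'   rate over the buffer-only rate, and its concentration dependence follows
#'   a two-parameter Michaelis-Menten law with half-saturation constant
#'   K_Fit and plateau k*_off,max.
#' @name kinetics
NULL

#' Relative fluorescence loss, Calibration = 100%
#'
#' `100 * (F_hyb_cond - F_post_cond) / (F_hyb_cal - F_post_cal)`; per-DA
#' losses are always computed within a sub-array and normalized to the same
#' DA on the Calibration sub-array.
#'
#' @param F_hyb_cond,F_post_cond Condition sub-array signals before and
#'   after incubation, RFU.
#' @param F_hyb_cal,F_post_cal Matching Calibration sub-array signals, RFU.
#' @return Percent loss; `NA` with an "uncalibratable" attribute-free result
#'   where the Calibration loss is not positive (signal gain between rounds).
#' @examples
#' relative_loss(1000, 960, 1000, 960) # 100
#' @export
relative_loss <- function(F_hyb_cond, F_post_cond, F_hyb_cal, F_post_cal) {
  cal_loss <- F_hyb_cal - F_post_cal
  out <- 100 * (F_hyb_cond - F_post_cond) / cal_loss
  out[!(cal_loss > 0)] <- NA_real_
  out
}

#' Handling-corrected survival fraction
#'
#' With `phi` the DA's fractional Calibration loss
#' (`(F_hyb_cal - F_post_cal) / F_hyb_cal`), the incubation-specific
#' survival is `S = F_post_cond / (F_hyb_cond * (1 - phi))`. Values above 1
#' (noise) are clipped to 1 and flagged.
#'
#' @param F_hyb_cond,F_post_cond Condition signals before/after incubation.
#' @param phi Calibration loss fraction for the same DA, in [0, 1).
#' @return Data frame with `survival`, `clipped`, `uncalibratable`.
#' @export
corrected_survival <- function(F_hyb_cond, F_post_cond, phi) {
  uncal <- !(phi < 1) | !(phi >= 0) | is.na(phi)
  s <- F_post_cond / (F_hyb_cond * (1 - phi))
  s[uncal] <- NA_real_
  clipped <- !is.na(s) & s > 1
  s[clipped] <- 1
  data.frame(survival = s, clipped = clipped, uncalibratable = uncal)
}

#' First-order dissociation rate from a survival fraction
#'
#' `k = -ln(S) / delta_t` (units 1/h for `delta_t` in hours): the
#' single-interval estimate of an exponential decay rate. Dissociation on
#' the dilute microarray surface is effectively irreversible, which is what
#' licenses the first-order form.
#'
#' @param S Survival fraction in (0, 1].
#' @param delta_t Incubation interval, hours (assay default 1 h).
#' @return Rate in 1/h.
#' @examples
#' rate_from_survival(exp(-1), 1) # 1
#' @export
rate_from_survival <- function(S, delta_t = 1) {
  if (any(!(delta_t > 0))) stop_violation("delta_t must be > 0")
  if (any(S <= 0, na.rm = TRUE)) {
    stop_violation("survival fraction <= 0: rate is unbounded")
  }
  -log(S) / delta_t
}

#' Ligand-induced (induced-fit) dissociation rate
#'
#' Total dissociation under ligand is the sum of the spontaneous and the
#' induced-fit rate, so `k*_off[Ligand] = k_total - k_off`. The raw signed
#' value is retained (it enters dose-response fits unfloored); a floored
#' display value is provided alongside.
#'
#' @param k_total_ligand Total rate under ligand incubation, 1/h.
#' @param k_off_buffer Spontaneous rate under buffer-only incubation, 1/h.
#' @return Data frame with `k_star` (raw), `k_star_floored`, `floored`.
#' @export
induced_fit_rate <- function(k_total_ligand, k_off_buffer) {
  k <- k_total_ligand - k_off_buffer
  data.frame(k_star = k, k_star_floored = pmax(k, 0),
             floored = !is.na(k) & k < 0)
}

#' Fit the induced-fit dose-response curve
#'
#' Unweighted least-squares fit of
#' `k* = k*_max [L] / (K_fit + [L])` by bounded Levenberg-Marquardt.
#' Initialization: `k*_max0` = max observed k*, `K_fit0` = geometric mean of
#' the concentrations; bounds `k*_max in [0, 10 k*_max0]`,
#' `K_fit in [1e-3 min[L], 1e3 max[L]]`.
#'
#' @param concentrations Molar ligand concentrations (>= 3 distinct, > 0).
#' @param k_star Induced-fit rates at those concentrations, 1/h (raw,
#'   unfloored values).
#' @return List: `K_fit`, `k_star_max`, `se_K_fit`, `se_k_star_max`, `rss`,
#'   `converged`, `flag` ("" / "all_zero" / "not_converged").
#' @examples
#' conc <- 10^seq(-6, -2, length.out = 8)
#' fit_dose_response(conc, 1.0 * conc / (2e-4 + conc))
#' @export
fit_dose_response <- function(concentrations, k_star) {
  ok <- !is.na(concentrations) & !is.na(k_star)
  conc <- concentrations[ok]; k <- k_star[ok]
  if (length(unique(conc)) < 3L || any(conc <= 0)) {
    stop_violation("need >= 3 distinct positive concentrations")
  }
  if (all(k <= 0)) {
    return(list(K_fit = NA_real_, k_star_max = 0, se_K_fit = NA_real_,
                se_k_star_max = NA_real_, rss = sum(k^2), converged = TRUE,
                flag = "all_zero"))
  }
  kmax0 <- max(k)
  K0 <- exp(mean(log(conc)))
  lower <- c(kmax = 0, K = 1e-3 * min(conc))
  upper <- c(kmax = 10 * kmax0, K = 1e3 * max(conc))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      k ~ kmax * conc / (K + conc),
      start = list(kmax = kmax0, K = K0),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(K_fit = NA_real_, k_star_max = NA_real_, se_K_fit = NA_real_,
                se_k_star_max = NA_real_, rss = NA_real_, converged = FALSE,
                flag = "not_converged"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kmax = NA_real_, K = NA_real_))
  conv <- fit$convInfo$isConv %||% TRUE
  list(K_fit = unname(cf["K"]), k_star_max = unname(cf["kmax"]),
       se_K_fit = unname(se["K"]), se_k_star_max = unname(se["kmax"]),
       rss = sum(stats::resid(fit)^2), converged = isTRUE(conv),
       flag = if (isTRUE(conv)) "" else "not_converged")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate dissociation rates from aggregated measurements
#'
#' Runs the full calibration chain on QC-aggregated measurements: pools
#' Calibration and BufferOnly signals across slides (multi-slide dilution
#' designs), derives the per-DA handling-loss fraction from the Calibration
#' sub-array, converts handling-corrected survivals to first-order rates,
#' and splits ligand-condition rates into spontaneous and induced-fit
#' components. Delta-method standard errors are propagated from the
#' replicate scatter of paired per-spot log post/hyb signal ratios, which
#' correctly cancels spot effects common to both imaging rounds (and, for
#' k*, the calibration terms common to the ligand and buffer rates).
#'
#' @param measurements Result of [qc_spots()] (preferred), or its
#'   `measurements` element alone (standard errors then fall back to a
#'   conservative unpaired approximation).
#' @param conditions Condition table (see [read_condition_table()]).
#' @return List of data frames: `calibrated` (per DA x sub-array:
#'   `relative_loss`, `survival`, `k_total`, flags), `rates` (per DA:
#'   `k_off`, `k_off_se`), `dose` (per DA x concentration: `k_star`,
#'   `k_star_floored`, `k_star_se`).
#' @export
estimate_rates <- function(measurements, conditions) {
  conditions <- validate_conditions(conditions)
  ratio_stats <- NULL
  if (is.list(measurements) && !is.data.frame(measurements) &&
      !is.null(measurements$measurements)) {
    ratio_stats <- measurements$ratio_stats
    measurements <- measurements$measurements
  }
  m <- pool_slides(measurements, conditions)
  m <- m[m$channel == "green" & !m$excluded, , drop = FALSE]
  cond_of <- c(stats::setNames(conditions$condition, conditions$subarray_id),
               "pooled:Calibration" = "Calibration",
               "pooled:BufferOnly" = "BufferOnly")
  conc_of <- stats::setNames(conditions$concentration,
                             conditions$subarray_id)
  dt_of <- stats::setNames(conditions$delta_t, conditions$subarray_id)
  delta_t <- unique(conditions$delta_t)
  if (length(delta_t) != 1L) {
    stop_violation("mixed delta_t across sub-arrays is not supported")
  }

  wide <- merge(
    stats::setNames(m[m$round == "post_hyb",
                      c("ace_id", "subarray_id", "mean_signal", "sd_signal",
                        "n_pass")],
                    c("ace_id", "subarray_id", "F_hyb", "sd_hyb", "n")),
    stats::setNames(m[m$round == "post_incubation",
                      c("ace_id", "subarray_id", "mean_signal", "sd_signal")],
                    c("ace_id", "subarray_id", "F_post", "sd_post")),
    by = c("ace_id", "subarray_id"))
  wide$condition <- cond_of[wide$subarray_id]

  cal <- wide[wide$condition == "Calibration", , drop = FALSE]
  cal$phi <- (cal$F_hyb - cal$F_post) / cal$F_hyb
  cal_of <- cal[, c("ace_id", "F_hyb", "F_post", "phi", "sd_hyb", "sd_post",
                    "n")]
  names(cal_of) <- c("ace_id", "F_hyb_cal", "F_post_cal", "phi",
                     "sd_hyb_cal", "sd_post_cal", "n_cal")

  cond <- wide[wide$condition != "Calibration", , drop = FALSE]
  cond <- merge(cond, cal_of, by = "ace_id")
  cond$relative_loss <- relative_loss(cond$F_hyb, cond$F_post,
                                      cond$F_hyb_cal, cond$F_post_cal)
  cs <- corrected_survival(cond$F_hyb, cond$F_post, cond$phi)
  cond$survival <- cs$survival
  cond$clipped <- cs$clipped
  cond$uncalibratable <- cs$uncalibratable
  cond$k_total <- NA_real_
  okS <- !is.na(cond$survival) & cond$survival > 0
  cond$k_total[okS] <- rate_from_survival(cond$survival[okS], delta_t)
  # variance of each sub-array's mean log survival ratio: from paired
  # per-replicate log(F_post/F_hyb) scatter when available (spot effects
  # common to both rounds cancel), else an unpaired fallback
  if (!is.null(ratio_stats)) {
    rs <- ratio_stats
    rs$condition <- cond_of[rs$subarray_id]
    # moderate the per-DA replicate variance toward the sub-array pooled
    # value (log-ratio noise is close to homoscedastic within an image);
    # with ~5 replicates the raw per-DA variance has so few degrees of
    # freedom that z statistics would have heavy t tails
    d <- pmax(rs$n_pairs - 1L, 0L)
    s2 <- ifelse(is.na(rs$sd_log_ratio), 0, rs$sd_log_ratio^2)
    pooled <- tapply(d * s2, rs$subarray_id, sum) /
      pmax(tapply(d, rs$subarray_id, sum), 1L)
    d0 <- 50
    s2_mod <- (d * s2 + d0 * pooled[rs$subarray_id]) / (d + d0)
    rs$v <- unname(s2_mod) / rs$n_pairs
    pool_v <- function(condition) {
      sub <- rs[rs$condition == condition, , drop = FALSE]
      agg <- stats::aggregate(v ~ ace_id, data = sub,
                              FUN = function(x) sum(x) / length(x)^2)
      stats::setNames(agg$v, agg$ace_id)
    }
    v_cal <- pool_v("Calibration")
    v_buf <- pool_v("BufferOnly")
    v_key <- stats::setNames(rs$v, paste(rs$ace_id, rs$subarray_id))
    cond$v_own <- ifelse(cond$condition == "Calibration", NA_real_,
                         ifelse(startsWith(cond$subarray_id, "pooled:"),
                                NA_real_,
                                v_key[paste(cond$ace_id, cond$subarray_id)]))
    cond$v_own[cond$subarray_id == "pooled:BufferOnly"] <-
      v_buf[cond$ace_id[cond$subarray_id == "pooled:BufferOnly"]]
    cond$k_se <- sqrt(cond$v_own + v_cal[cond$ace_id]) / delta_t
  } else {
    rel <- function(sd, mu, n) {
      ifelse(mu > 0, (sd / mu)^2 / pmax(n, 1), NA_real_)
    }
    cond$v_own <- rel(cond$sd_post, cond$F_post, cond$n) +
      rel(cond$sd_hyb, cond$F_hyb, cond$n)
    cond$k_se <- sqrt(cond$v_own +
                        rel(cond$sd_post_cal, cond$F_post_cal, cond$n_cal) +
                        rel(cond$sd_hyb_cal, cond$F_hyb_cal, cond$n_cal)) /
      delta_t
  }

  buf <- cond[cond$condition == "BufferOnly",
              c("ace_id", "k_total", "k_se", "v_own")]
  names(buf) <- c("ace_id", "k_off", "k_off_se", "v_buf")
  buf$k_off_floored <- pmax(buf$k_off, 0)

  lig <- cond[cond$condition == "Ligand", , drop = FALSE]
  lig$concentration <- conc_of[lig$subarray_id]
  lig <- merge(lig, buf, by = "ace_id")
  ifr <- induced_fit_rate(lig$k_total, lig$k_off)
  lig$k_star <- ifr$k_star
  lig$k_star_floored <- ifr$k_star_floored
  # the calibration ratio is common to both rates and cancels in k*
  lig$k_star_se <- sqrt(lig$v_own + lig$v_buf) / delta_t

  calibrated <- cond[, c("ace_id", "subarray_id", "condition",
                         "relative_loss", "survival", "clipped",
                         "uncalibratable", "k_total", "k_se")]
  dose <- lig[, c("ace_id", "subarray_id", "concentration", "k_star",
                  "k_star_floored", "k_star_se")]
  dose <- dose[order(dose$ace_id, dose$concentration), ]
  rates <- buf[, c("ace_id", "k_off", "k_off_se", "k_off_floored")]
  rownames(calibrated) <- rownames(dose) <- rownames(rates) <- NULL
  list(calibrated = calibrated, rates = rates, dose = dose)
}

#' Fit K_Fit and k*_off,max per DA across a dilution series
#'
#' @param dose `dose` element of [estimate_rates()].
#' @param min_points Minimum distinct concentrations required per DA.
#' @return Data frame per DA: `K_fit`, `k_star_max`, standard errors, `rss`,
#'   `converged`, `flag`.
#' @export
fit_landscape <- function(dose, min_points = 3L) {
  out <- lapply(split(dose, dose$ace_id), function(d) {
    if (length(unique(d$concentration)) < min_points) return(NULL)
    f <- fit_dose_response(d$concentration, d$k_star)
    data.frame(ace_id = d$ace_id[1], K_fit = f$K_fit,
               k_star_max = f$k_star_max, se_K_fit = f$se_K_fit,
               se_k_star_max = f$se_k_star_max, rss = f$rss,
               converged = f$converged, flag = f$flag,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
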