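#' @title Spot quality control and replicate aggregation
#' @description The three spot-rejection rules are evaluated on the
#'   post-hybridization green image of each sub-array, and a spot flagged
#'   there is excluded from all imaging rounds: (1) low hybridization signal,
#'   strictly below 200 RFU (the table's median pixel statistic stands in for
#'   the pixel mean, as pixel-level data are not retained); (2) poor
#'   morphology, where the spot's pixel coefficient of variation exceeds the
#'   sub-array mean CV by more than three sample standard deviations;
#'   (3) high local background, exceeding the sub-array background mean by
#'   more than three sample standard deviations. An ACE whose passing
#'   replicate count drops below `min_pass` in any sub-array is excluded
#'   from the dataset everywhere.
#' @name qc
NULL

#' Flag spots with low hybridization signal
#'
#' @param signal Post-hybridization green signal(s), RFU.
#' @param threshold Rejection threshold in RFU; strictly-below comparison.
#' @return Logical vector, `TRUE` = flagged.
#' @examples
#' flag_low_signal(c(199.9, 200, 5000)) # TRUE FALSE FALSE
#' @export
flag_low_signal <- function(signal, threshold = 200) {
  signal < threshold
}

#' Flag spots with outlying pixel coefficient of variation
#'
#' Operates on all spots of one sub-array image; spot i is flagged iff
#' `CV_i > mean(CV) + 3 * sd(CV)` with CV = pixel_sd / median_signal and
#' `sd` the sample (n-1) standard deviation. Scale-free: rescaling all
#' signals leaves the flags unchanged.
#'
#' @param median_signal,pixel_sd Per-spot signal statistics of one sub-array.
#' @return Logical vector, `TRUE` = flagged.
#' @export
flag_morphology <- function(median_signal, pixel_sd) {
  if (length(median_signal) < 2L) stop_violation("need >= 2 spots for the CV rule")
  if (any(!(median_signal > 0))) {
    stop_violation("undefined CV: non-positive median signal in sub-array")
  }
  cv <- pixel_sd / median_signal
  cv > mean(cv) + 3 * stats::sd(cv)
}

#' Flag spots with outlying local background
#'
#' Spot i is flagged iff
#' `background_i > mean(background) + 3 * sd(background)` over all spots of
#' the sub-array.
#'
#' @param background_mean Per-spot local background means of one sub-array.
#' @return Logical vector, `TRUE` = flagged.
#' @export
flag_background <- function(background_mean) {
  if (length(background_mean) < 2L) {
    stop_violation("need >= 2 spots for the background rule")
  }
  background_mean > mean(background_mean) + 3 * stats::sd(background_mean)
}

#' Apply spot QC and aggregate replicates
#'
#' Flags are computed on the post-hybridization green records of each
#' sub-array; the passing replicate set of each (ACE, sub-array) then
#' determines which spots contribute in every round and channel. Per
#' (ACE, sub-array, round, channel) the mean and sd over passing replicates
#' are reported; ACEs with fewer than `min_pass` passing replicates in any
#' sub-array are marked `excluded` dataset-wide and their means set to `NA`
#' (they propagate as blank heat-map tiles downstream).
#'
#' @param spots Spot data frame (see [read_intensity_table()]).
#' @param threshold Low-signal threshold, RFU.
#' @param min_pass Minimum passing replicates per sub-array.
#' @return List with `flags` (per post-hyb green spot: the three flags and
#'   `pass`), `measurements` (per ACE/sub-array/round/channel:
#'   `mean_signal`, `sd_signal`, `n_pass`, `excluded`) and `ratio_stats`
#'   (per ACE/sub-array: replicate scatter of the paired per-spot log
#'   post/hyb signal ratio, used for rate standard errors).
#' @export
qc_spots <- function(spots, threshold = 200, min_pass = 3L) {
  spots <- validate_spots(spots)
  hyb <- spots[spots$round == "post_hyb" & spots$channel == "green", ,
               drop = FALSE]
  if (nrow(hyb) == 0L) stop_violation("no post-hybridization green spots")
  grp <- interaction(hyb$slide_id, hyb$subarray_id, drop = TRUE)
  morph <- bg <- logical(nrow(hyb))
  for (g in levels(grp)) {
    i <- which(grp == g)
    morph[i] <- flag_morphology(hyb$median_signal[i], hyb$pixel_sd[i])
    bg[i] <- flag_background(hyb$background_mean[i])
  }
  flags <- data.frame(
    slide_id = hyb$slide_id, subarray_id = hyb$subarray_id,
    ace_id = hyb$ace_id, replicate = hyb$replicate,
    low_signal = flag_low_signal(hyb$median_signal, threshold),
    bad_morphology = morph, high_background = bg,
    stringsAsFactors = FALSE)
  flags$pass <- !(flags$low_signal | flags$bad_morphology |
                    flags$high_background)

  key <- function(d) paste(d$slide_id, d$subarray_id, d$ace_id, d$replicate,
                           sep = "\r")
  pass_of <- stats::setNames(flags$pass, key(flags))
  spots$pass <- pass_of[key(spots)]
  spots$pass[is.na(spots$pass)] <- FALSE # spots with no post-hyb record fail

  passing <- spots[spots$pass, , drop = FALSE]
  meas <- stats::aggregate(
    median_signal ~ ace_id + subarray_id + slide_id + round + channel,
    data = passing, FUN = mean)
  names(meas)[names(meas) == "median_signal"] <- "mean_signal"
  sds <- stats::aggregate(
    median_signal ~ ace_id + subarray_id + slide_id + round + channel,
    data = passing, FUN = function(x) if (length(x) > 1) stats::sd(x) else 0)
  names(sds)[names(sds) == "median_signal"] <- "sd_signal"
  npass <- stats::aggregate(
    median_signal ~ ace_id + subarray_id + slide_id + round + channel,
    data = passing, FUN = length)
  names(npass)[names(npass) == "median_signal"] <- "n_pass"
  meas <- merge(merge(meas, sds), npass)

  # exclusion is decided on the post-hyb green pass counts per sub-array,
  # including sub-arrays where *zero* replicates passed
  pc <- stats::aggregate(pass ~ ace_id + subarray_id + slide_id, data = flags,
                         FUN = sum)
  excluded_aces <- unique(pc$ace_id[pc$pass < min_pass])
  meas$excluded <- meas$ace_id %in% excluded_aces
  meas$mean_signal[meas$excluded] <- NA_real_
  meas <- meas[, c("ace_id", "subarray_id", "slide_id", "round", "channel",
                   "mean_signal", "sd_signal", "n_pass", "excluded")]
  meas <- meas[order(meas$slide_id, meas$subarray_id, meas$ace_id, meas$round,
                     meas$channel), ]
  rownames(meas) <- NULL

  # replicate scatter of the paired per-spot log survival ratio
  # log(F_post_i / F_hyb_i): multiplicative spot effects are common to both
  # rounds, so this is the right dispersion for rate standard errors
  green <- passing[passing$channel == "green", , drop = FALSE]
  h <- green[green$round == "post_hyb",
             c("ace_id", "subarray_id", "slide_id", "replicate",
               "median_signal")]
  p <- green[green$round == "post_incubation",
             c("ace_id", "subarray_id", "slide_id", "replicate",
               "median_signal")]
  pr <- merge(h, p, by = c("ace_id", "subarray_id", "slide_id", "replicate"),
              suffixes = c("_hyb", "_post"))
  ratio_stats <- NULL
  if (nrow(pr)) {
    pr$log_ratio <- log(pr$median_signal_post / pr$median_signal_hyb)
    ratio_stats <- stats::aggregate(
      log_ratio ~ ace_id + subarray_id + slide_id, data = pr,
      FUN = function(x) c(sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                          n = length(x)))
    ratio_stats <- data.frame(
      ratio_stats[c("ace_id", "subarray_id", "slide_id")],
      sd_log_ratio = ratio_stats$log_ratio[, "sd"],
      n_pairs = as.integer(ratio_stats$log_ratio[, "n"]),
      stringsAsFactors = FALSE)
  }
  list(flags = flags, measurements = meas, ratio_stats = ratio_stats)
}
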