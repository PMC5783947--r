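#' @title Spot-level data model and table IO
#' @description Native tables are UTF-8 TSV with a versioned comment header
#'   line (`# acekit <kind> v1`); `NA` encodes missing; numeric fields are
#'   serialized at full (17 significant digit) precision so write/read round
#'   trips are lossless. A GenePix-style `genepix_gpr` reading dialect is
#'   provided as a best-effort convenience for deposited scanner exports.
#' @name array_io
NULL

SPOT_COLUMNS <- c("subarray_id", "slide_id", "ace_id", "replicate", "round",
                  "channel", "median_signal", "pixel_sd", "background_mean",
                  "grid_row", "grid_col")
COND_COLUMNS <- c("subarray_id", "slide_id", "condition", "ligand_name",
                  "concentration", "temperature", "delta_t", "buffer_label")

fmt_cell <- function(x) {
  if (is.double(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else sprintf("%.17g", v)
    }, character(1))
    out
  } else {
    as.character(x)
  }
}

write_native_table <- function(df, path, kind) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# acekit %s v1", kind), con)
  out <- as.data.frame(lapply(df, fmt_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  suppressWarnings(utils::write.table(
    out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"))
  invisible(path)
}

read_native_table <- function(path, kind = NULL) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  skip <- if (startsWith(first, "#")) 1L else 0L
  if (!is.null(kind) && skip == 1L &&
      !grepl(paste0("^# acekit ", kind, " v"), first)) {
    stop_io("'%s' is not an acekit %s table (header: %s)", path, kind, first)
  }
  utils::read.delim(path, skip = skip, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a spot-intensity table
#'
#' @param path File path.
#' @param dialect `"native"` (acekit schema) or `"genepix_gpr"` (maps
#'   `Block` to sub-array, `Name` to ACE id, `F532 Median`/`F532 SD`/
#'   `B532 Mean` to the signal statistics; replicate indices are assigned in
#'   file order within each block).
#' @param round,channel Imaging round and channel assigned to every record
#'   of a GPR file (one GPR per image); ignored for the native dialect.
#' @param slide_id Slide label for GPR records (native files carry their own).
#' @return Typed spot data frame with columns
#'   `r paste(SPOT_COLUMNS, collapse = ", ")`.
#' @export
read_intensity_table <- function(path, dialect = c("native", "genepix_gpr"),
                                 round = "post_hyb", channel = "green",
                                 slide_id = "slide1") {
  dialect <- match.arg(dialect)
  if (dialect == "native") {
    df <- read_native_table(path, "spots")
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "")
    need <- c("Block", "Row", "Column", "Name", "F532 Median", "F532 SD",
              "B532 Mean")
    missing <- setdiff(need, names(raw))
    if (length(missing)) {
      stop_io("GPR file lacks columns: %s", paste(missing, collapse = ", "))
    }
    df <- data.frame(
      subarray_id = sprintf("sa%d", as.integer(raw$Block)),
      slide_id = slide_id,
      ace_id = raw$Name,
      replicate = stats::ave(seq_len(nrow(raw)),
                             raw$Block, raw$Name, FUN = seq_along),
      round = round, channel = channel,
      median_signal = as.numeric(raw$`F532 Median`),
      pixel_sd = as.numeric(raw$`F532 SD`),
      background_mean = as.numeric(raw$`B532 Mean`),
      grid_row = as.integer(raw$Row), grid_col = as.integer(raw$Column),
      stringsAsFactors = FALSE)
  }
  validate_spots(df, path)
}

validate_spots <- function(df, path = "<in-memory>") {
  missing <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing)) {
    stop_io("spot table %s lacks mandatory columns: %s", path,
            paste(missing, collapse = ", "))
  }
  for (col in c("median_signal", "pixel_sd", "background_mean")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | v < 0)
    if (length(bad)) {
      stop_io("spot table %s: %s invalid (negative or unparseable) at row %d",
              path, col, bad[1])
    }
    df[[col]] <- v
  }
  key <- interaction(df$slide_id, df$subarray_id, df$grid_row, df$grid_col,
                     df$round, df$channel, drop = TRUE)
  if (anyDuplicated(key)) {
    stop_io("spot table %s: duplicate (subarray, grid, round, channel) key at row %d",
            path, anyDuplicated(key))
  }
  df[, c(SPOT_COLUMNS, setdiff(names(df), SPOT_COLUMNS))]
}

#' Write a spot-intensity table (native dialect)
#' @param spots Spot data frame.
#' @param path Output path.
#' @export
write_intensity_table <- function(spots, path) {
  validate_spots(spots)
  write_native_table(spots[, SPOT_COLUMNS], path, "spots")
}

#' Read a sub-array condition table
#'
#' Conditions are `Calibration` (left unincubated; defines the 100%
#' fluorescence-loss reference), `BufferOnly` (defines spontaneous k_off) or
#' `Ligand` with a positive molar concentration. Exactly one Calibration
#' sub-array per slide is enforced.
#'
#' @param path File path.
#' @return Condition data frame with columns
#'   `r paste(COND_COLUMNS, collapse = ", ")`.
#' @export
read_condition_table <- function(path) {
  validate_conditions(read_native_table(path, "conditions"), path)
}

validate_conditions <- function(df, path = "<in-memory>") {
  missing <- setdiff(COND_COLUMNS, names(df))
  if (length(missing)) {
    stop_io("condition table %s lacks mandatory columns: %s", path,
            paste(missing, collapse = ", "))
  }
  ok_cond <- df$condition %in% c("Calibration", "BufferOnly", "Ligand")
  if (any(!ok_cond)) {
    stop_io("condition table %s: unknown condition '%s'", path,
            df$condition[!ok_cond][1])
  }
  for (slide in unique(df$slide_id)) {
    n_cal <- sum(df$condition == "Calibration" & df$slide_id == slide)
    if (n_cal != 1L) {
      stop_io("slide '%s' has %d Calibration sub-arrays (need exactly 1)",
              slide, n_cal)
    }
  }
  if (any(df$condition == "Ligand" & !(df$concentration > 0))) {
    stop_io("Ligand rows must carry concentration > 0")
  }
  if (any(!(df$delta_t > 0))) stop_io("delta_t must be > 0")
  df
}

#' Write a sub-array condition table
#' @param conditions Condition data frame.
#' @param path Output path.
#' @export
write_condition_table <- function(conditions, path) {
  validate_conditions(conditions)
  write_native_table(conditions[, COND_COLUMNS], path, "conditions")
}

#' Write / read a landscape table
#'
#' Long-form TSV: `ace_id, start5, length, mismatch_pos, value,
#' n_replicates, qc_flag`; `NA` encodes missing (QC-excluded) values. The
#' round trip is lossless.
#'
#' @param landscape Landscape data frame (see [as_landscape()]).
#' @param path File path.
#' @return `write_landscape_table()` returns `path` invisibly;
#'   `read_landscape_table()` returns the data frame.
#' @export
write_landscape_table <- function(landscape, path) {
  cols <- c("ace_id", "start5", "length", "mismatch_pos", "value",
            "n_replicates", "qc_flag")
  for (col in setdiff(cols, names(landscape))) {
    landscape[[col]] <- if (col == "qc_flag") "" else NA
  }
  df <- landscape[, cols, drop = FALSE]
  df$value <- as.double(df$value)
  write_native_table(df, path, "landscape")
}

#' @rdname write_landscape_table
#' @export
read_landscape_table <- function(path) {
  df <- read_native_table(path, "landscape")
  df$qc_flag[is.na(df$qc_flag)] <- ""
  df
}

#' Pool calibration-role measurements across slides
#'
#' For multi-slide dilution series the Calibration and BufferOnly signals of
#' each DA are averaged across slides (keyed on `ace_id`, round and channel)
#' before rate computation; ligand sub-arrays are left per-slide.
#'
#' @param measurements Aggregated DA measurements (see [qc_spots()]).
#' @param conditions Condition table.
#' @return Measurements with Calibration/BufferOnly rows replaced by pooled
#'   rows (subarray_id `pooled:<condition>`).
#' @export
pool_slides <- function(measurements, conditions) {
  cond_of <- stats::setNames(conditions$condition, conditions$subarray_id)
  m <- measurements
  m$condition <- cond_of[m$subarray_id]
  pool <- m$condition %in% c("Calibration", "BufferOnly")
  keep <- m[!pool, , drop = FALSE]
  if (!any(pool)) return(measurements)
  p <- m[pool, , drop = FALSE]
  agg <- stats::aggregate(
    cbind(mean_signal, sd_signal) ~ ace_id + condition + round + channel,
    data = p, FUN = mean, na.action = stats::na.pass)
  npass <- stats::aggregate(n_pass ~ ace_id + condition + round + channel,
                            data = p, FUN = min)
  excl <- stats::aggregate(excluded ~ ace_id + condition + round + channel,
                           data = p, FUN = any)
  agg <- merge(merge(agg, npass), excl)
  agg$subarray_id <- paste0("pooled:", agg$condition)
  agg$slide_id <- "pooled"
  rbind(keep[, names(keep) != "condition", drop = FALSE],
        agg[, setdiff(names(keep), "condition"), drop = FALSE])
}
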