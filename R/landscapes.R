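#' @title Landscape assembly: heat maps and linear maps
#' @description A landscape is a map from ACE design coordinates
#'   `(start5, length[, mismatch_pos])` to a scalar (hybridization signal,
#'   k_off, k*_off, K_fit, ...), held as a long data frame with attributes
#'   `kind` and `aptamer_id`. Missing (QC-excluded) values are `NA` and
#'   render as blank heat-map tiles; means over contributors always skip
#'   missing values and a cell with zero contributors is missing, never 0.
#' @name landscapes
NULL

#' Build a landscape from designs and values
#'
#' @param designs Design table rows ([ace_design]).
#' @param values Numeric vector aligned with `designs` (NA = missing).
#' @param kind Scalar label, e.g. `"hybridization"`, `"k_off"`,
#'   `"k_star_off"`, `"K_fit"`, `"k_star_max"`, `"two_color_ratio"`.
#' @param n_replicates,qc_flag Optional per-design annotations.
#' @return Landscape data frame.
#' @export
as_landscape <- function(designs, values, kind,
                         n_replicates = NA_integer_, qc_flag = "") {
  ls <- data.frame(ace_id = designs$ace_id, start5 = designs$start5,
                   length = designs$length,
                   mismatch_pos = designs$mismatch_pos,
                   value = as.double(values),
                   n_replicates = n_replicates, qc_flag = qc_flag,
                   stringsAsFactors = FALSE)
  attr(ls, "kind") <- kind
  attr(ls, "aptamer_id") <- designs$aptamer_id[1]
  ls
}

all_coords <- function(aptamer) {
  index_to_coord(seq_len(aptamer$length), aptamer)
}

#' 5'-anchored heat-map matrix
#'
#' Rows are aptamer coordinates of the 5'-most duplexed base (ascending),
#' columns ACE lengths (ascending); the cell (N, L) holds the value of
#' `5'_N:L`. Absent or excluded designs are `NA` cells. Ordering is a
#' property of the aptamer, not of input row order.
#'
#' @param landscape Landscape data frame ([as_landscape()]); mismatch rows
#'   are ignored here (see [build_mismatch_map()]).
#' @param aptamer The matching [aptamer_construct()].
#' @return Numeric matrix with dimnames `start5` x `length`.
#' @export
build_heatmap_5p <- function(landscape, aptamer) {
  build_anchor_map(landscape, aptamer, anchor = "5p")
}

#' 3'-anchored heat-map matrix
#'
#' Rows are coordinates of the 3'-most duplexed base: `N3 = N5 + L - 1` in
#' skip-zero arithmetic.
#'
#' @inheritParams build_heatmap_5p
#' @return Numeric matrix with dimnames `start3` x `length`.
#' @export
build_heatmap_3p <- function(landscape, aptamer) {
  build_anchor_map(landscape, aptamer, anchor = "3p")
}

build_anchor_map <- function(landscape, aptamer, anchor) {
  pm <- landscape[is.na(landscape$mismatch_pos), , drop = FALSE]
  lens <- sort(unique(pm$length))
  coords <- all_coords(aptamer)
  mat <- matrix(NA_real_, nrow = length(coords), ncol = length(lens),
                dimnames = list(as.character(coords), as.character(lens)))
  if (nrow(pm) == 0L) return(mat)
  i0 <- coord_to_index(pm$start5, aptamer)
  row_coord <- if (anchor == "5p") pm$start5 else {
    index_to_coord(i0 + pm$length - 1L, aptamer)
  }
  mat[cbind(match(row_coord, coords), match(pm$length, lens))] <- pm$value
  mat
}

#' Enantio (paired 5'/3') heat-map view
#'
#' Juxtaposes the 5'-anchored and 3'-anchored matrices; each DA appears
#' exactly once in each, and diagonals of the 5' view correspond to rows of
#' the 3' view (DAs sharing a 3' duplex start site). The 5' -> 3' -> 5'
#' round trip is the identity.
#'
#' @inheritParams build_heatmap_5p
#' @return List with matrices `map_5p` and `map_3p`.
#' @export
build_enantio <- function(landscape, aptamer) {
  list(map_5p = build_heatmap_5p(landscape, aptamer),
       map_3p = build_heatmap_3p(landscape, aptamer))
}

#' Mismatch heat-map matrix
#'
#' Rows are length-`length` windows `5'_N:L` (ascending N), columns the
#' aptamer coordinate of the mismatched base; only in-window columns are
#' populated. The extra leftmost `PM` column holds the perfect-match
#' (L-1)-mer sharing the window's 3' end (i.e. row `5'_N:L` gets
#' `5'_{N+1}:{L-1}`), the structural analogue of a 5'-terminally mismatched
#' L-mer. Degenerate-flagged designs are rendered missing.
#'
#' @param landscape Landscape containing mismatch rows (and, for the PM
#'   column, perfect-match (L-1)-mer rows).
#' @param length ACE length of the mismatch scan.
#' @param aptamer The matching [aptamer_construct()].
#' @param degenerate Optional logical vector aligned with `landscape` rows
#'   marking substitution fixed points to blank out.
#' @return Numeric matrix, rows `5'_N:L`, columns `PM` then coordinates.
#' @export
build_mismatch_map <- function(landscape, length, aptamer,
                               degenerate = NULL) {
  mm <- landscape[!is.na(landscape$mismatch_pos) &
                    landscape$length == length, , drop = FALSE]
  if (!is.null(degenerate)) {
    mm <- mm[!degenerate[!is.na(landscape$mismatch_pos) &
                           landscape$length == length], , drop = FALSE]
  }
  coords <- all_coords(aptamer)
  starts <- coords[seq_len(aptamer$length - length + 1L)]
  mat <- matrix(NA_real_, nrow = base::length(starts),
                ncol = base::length(coords) + 1L,
                dimnames = list(sprintf("5'_%d:%d", starts, length),
                                c("PM", as.character(coords))))
  if (nrow(mm)) {
    mat[cbind(match(mm$start5, starts),
              match(mm$mismatch_pos, coords) + 1L)] <- mm$value
  }
  pm <- landscape[is.na(landscape$mismatch_pos) &
                    landscape$length == length - 1L, , drop = FALSE]
  if (nrow(pm)) {
    # (L-1)-mer starting one base in shares the row window's 3' end
    i_next <- coord_to_index(starts, aptamer) + 1L
    pm_start <- index_to_coord(i_next, aptamer)
    mat[, "PM"] <- pm$value[match(pm_start, pm$start5)]
  }
  mat
}

#' Forward linear map: per-ACE values onto aptamer bases
#'
#' `covers_base` mode averages, per aptamer coordinate, the values of all
#' ACEs whose duplex window covers that base; `mismatch_at_base` mode
#' averages only ACEs whose mismatch coordinate equals the base. Bases with
#' no contributors are `NA`.
#'
#' @param landscape Landscape data frame.
#' @param aptamer The matching [aptamer_construct()].
#' @param mode `"covers_base"` or `"mismatch_at_base"`.
#' @return Named numeric vector over aptamer coordinates.
#' @export
forward_linear_map <- function(landscape, aptamer,
                               mode = c("covers_base", "mismatch_at_base")) {
  mode <- match.arg(mode)
  coords <- all_coords(aptamer)
  out <- stats::setNames(rep(NA_real_, length(coords)), coords)
  ls <- landscape[!is.na(landscape$value), , drop = FALSE]
  if (nrow(ls) == 0L) return(out)
  if (mode == "mismatch_at_base") {
    ls <- ls[!is.na(ls$mismatch_pos), , drop = FALSE]
    agg <- tapply(ls$value, ls$mismatch_pos, mean)
    out[names(agg)] <- agg
  } else {
    i0 <- coord_to_index(ls$start5, aptamer)
    idx <- unlist(mapply(function(a, n) a:(a + n - 1L), i0, ls$length,
                         SIMPLIFY = FALSE))
    vals <- rep(ls$value, times = ls$length)
    agg <- tapply(vals, index_to_coord(idx, aptamer), mean)
    out[names(agg)] <- agg
  }
  out[as.character(coords)]
}

#' Reverse linear map: per-base scores onto ACEs
#'
#' Each ACE receives the mean score over the aptamer bases its duplex
#' window covers.
#'
#' @param per_base_scores Named numeric vector over aptamer coordinates
#'   (names are coordinates; skip-zero).
#' @param designs Design table.
#' @param aptamer The matching [aptamer_construct()].
#' @return Numeric vector aligned with `designs`.
#' @export
reverse_linear_map <- function(per_base_scores, designs, aptamer) {
  vapply(seq_len(nrow(designs)), function(r) {
    i0 <- coord_to_index(designs$start5[r], aptamer)
    cc <- index_to_coord(i0:(i0 + designs$length[r] - 1L), aptamer)
    mean(per_base_scores[as.character(cc)], na.rm = TRUE)
  }, numeric(1))
}

#' Two-color (red / green) normalization
#'
#' Ratio of the post-incubation red (labelled-ligand) signal to the
#' post-incubation green (aptamer) signal of the same DA: a per-DA measure
#' of ligand occupancy corrected for the number of surviving DA molecules.
#'
#' @param red_post,green_post Post-incubation signals, RFU.
#' @return Data frame with `ratio` (`NA` where green <= 0) and `flag`.
#' @examples
#' two_color_normalize(500, 1000)$ratio # 0.5
#' @export
two_color_normalize <- function(red_post, green_post) {
  bad <- !(green_post > 0)
  ratio <- red_post / green_post
  ratio[bad] <- NA_real_
  data.frame(ratio = ratio, flag = ifelse(bad, "nonpositive_green", ""))
}
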