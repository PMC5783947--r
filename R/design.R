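#' @title ACE library design
#' @description Enumerate, count, name and lay out aptamer-complementary
#'   element (ACE) libraries tiling an aptamer. A design table (one row per
#'   ACE) is the package's working representation: columns `aptamer_id`,
#'   `ace_id` (canonical 5'-anchored name), `start5`, `length`,
#'   `mismatch_pos` (NA for perfect match), `degenerate`, `spacer3_len`,
#'   `linker5_len`.
#' @name ace_design
NULL

new_design_table <- function(aptamer, start5, length, mismatch_pos,
                             spacer3_len, linker5_len) {
  d <- data.frame(
    aptamer_id = rep(aptamer$id, length.out = max(1L, base::length(start5))),
    start5 = as.integer(start5), length = as.integer(length),
    mismatch_pos = as.integer(mismatch_pos),
    stringsAsFactors = FALSE)[seq_along(start5), , drop = FALSE]
  d$degenerate <- mismatch_degenerate(d, aptamer)
  d$spacer3_len <- as.integer(spacer3_len)
  d$linker5_len <- as.integer(linker5_len)
  d$ace_id <- format_name(d, aptamer, anchor = "5p")
  rownames(d) <- NULL
  d[, c("aptamer_id", "ace_id", "start5", "length", "mismatch_pos",
        "degenerate", "spacer3_len", "linker5_len")]
}

#' Enumerate perfect-match ACEs
#'
#' Every complementary window of every length in `[min_len, max_len]`; a
#' length-N scan of an L-base aptamer yields L - N + 1 designs.
#'
#' @param aptamer An [aptamer_construct()].
#' @param min_len,max_len Inclusive ACE length range.
#' @param spacer3_len Number of 3' T spacer bases on each probe (default 25).
#' @param linker5_len Number of 5' T linker bases (default 0).
#' @return Design table (see [ace_design]).
#' @examples
#' nrow(enumerate_perfect_match(atp_dna_construct(), 7, 12)) # 141
#' @export
enumerate_perfect_match <- function(aptamer, min_len, max_len,
                                    spacer3_len = 25L, linker5_len = 0L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len < 1L || min_len > max_len) {
    stop_violation("need 1 <= min_len <= max_len (got %d..%d)",
                   min_len, max_len)
  }
  if (max_len > aptamer$length) {
    stop_violation("ACE length %d exceeds aptamer length %d",
                   max_len, aptamer$length)
  }
  lens <- rep(min_len:max_len,
              times = aptamer$length - (min_len:max_len) + 1L)
  i0 <- unlist(lapply(min_len:max_len,
                      function(n) seq_len(aptamer$length - n + 1L)))
  new_design_table(aptamer, index_to_coord(i0, aptamer), lens,
                   NA_integer_, spacer3_len, linker5_len)
}

#' Enumerate single-mismatch ACEs
#'
#' For each window of each requested length, one design per in-window
#' position (termini included). The mismatching probe base is A when the
#' perfect-match probe base is G, C or T, and T when it is A, producing
#' A-C, A-G, A-A and T-T mismatches against the aptamer.
#'
#' @inheritParams enumerate_perfect_match
#' @param lengths Integer vector of ACE lengths.
#' @return Design table; `mismatch_pos` holds the aptamer coordinate of the
#'   mismatched base. Substitution fixed points (substitute equals the
#'   original probe base, impossible under the A/T rule on pure sequences)
#'   would be flagged `degenerate` rather than dropped, so enumerated sizes
#'   always match [count_single_mismatch()].
#' @examples
#' nrow(enumerate_single_mismatch(atp_dna_construct(), 12)) # 252
#' @export
enumerate_single_mismatch <- function(aptamer, lengths,
                                      spacer3_len = 25L, linker5_len = 0L) {
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 1L)) stop_violation("ACE lengths must be >= 1")
  if (any(lengths > aptamer$length)) {
    stop_violation("ACE length %d exceeds aptamer length %d",
                   max(lengths), aptamer$length)
  }
  rows <- lapply(lengths, function(n) {
    i0 <- rep(seq_len(aptamer$length - n + 1L), each = n)
    off <- rep(seq_len(n) - 1L, times = aptamer$length - n + 1L)
    cbind(i0 = i0, len = n, mm_idx = i0 + off)
  })
  m <- do.call(rbind, rows)
  new_design_table(aptamer, index_to_coord(m[, "i0"], aptamer), m[, "len"],
                   index_to_coord(m[, "mm_idx"], aptamer),
                   spacer3_len, linker5_len)
}

# TRUE where the substituted probe base equals the perfect-match probe base
mismatch_degenerate <- function(designs, aptamer) {
  out <- rep(FALSE, nrow(designs))
  has_mm <- !is.na(designs$mismatch_pos)
  if (!any(has_mm)) return(out)
  apt_base <- aptamer_base(aptamer, designs$mismatch_pos[has_mm])
  pm <- complement_base(apt_base)
  out[has_mm] <- pm == mismatch_substitute(pm)
  out
}

complement_base <- function(base) {
  # probes are synthesized DNA, so complements are always in the DNA alphabet
  # (RNA U pairs with A)
  unname(c(A = "T", C = "G", G = "C", T = "A", U = "A")[base])
}

mismatch_substitute <- function(pm_base) {
  ifelse(pm_base == "A", "T", "A")
}

#' Closed-form count of perfect-match ACEs
#'
#' Number of perfect-match windows of lengths `X..Y` on an aptamer of length
#' `L`: `[(Y - X + 1)(2L + 1) - Y^2 + (X - 1)^2] / 2`. For a single length N
#' this reduces to `L - N + 1`, and for `X = 1` to `[Y(2L + 1) - Y^2] / 2`.
#'
#' @param L Aptamer length.
#' @param X,Y Inclusive ACE length bounds, `1 <= X <= Y <= L`.
#' @return Integer count.
#' @examples
#' count_perfect_match(32, 7, 12) # 141
#' @export
count_perfect_match <- function(L, X, Y) {
  check_count_bounds(L, X, Y)
  as.integer(((Y - X + 1) * (2 * L + 1) - Y^2 + (X - 1)^2) / 2)
}

#' Closed-form count of single-mismatch ACEs
#'
#' Number of (window, mismatch position) pairs for ACE lengths `X..Y` on an
#' aptamer of length `L`:
#' `[Y(Y + 1)(3L - 2Y + 2) - X(X - 1)(3L - 2X + 4)] / 6`. For a single
#' length Y this reduces to `Y(L - Y + 1)`.
#'
#' @inheritParams count_perfect_match
#' @return Integer count.
#' @examples
#' count_single_mismatch(32, 12, 12) # 252
#' @export
count_single_mismatch <- function(L, X, Y) {
  check_count_bounds(L, X, Y)
  as.integer((Y * (Y + 1) * (3 * L - 2 * Y + 2) -
                X * (X - 1) * (3 * L - 2 * X + 4)) / 6)
}

check_count_bounds <- function(L, X, Y) {
  stopifnot(length(L) == 1L, length(X) == 1L, length(Y) == 1L)
  if (!(X >= 1 && X <= Y && Y <= L)) {
    stop_violation("need 1 <= X <= Y <= L (got X=%s, Y=%s, L=%s)", X, Y, L)
  }
  invisible(TRUE)
}

#' Probe sequence of an ACE design
#'
#' 5'->3' DNA probe: `T x linker5_len`, then the reverse complement of the
#' aptamer window (RNA aptamers are complemented in the DNA alphabet, U -> A)
#' with any single-mismatch substitution applied, then `T x spacer3_len`.
#'
#' @param designs Design table rows.
#' @param aptamer The matching [aptamer_construct()].
#' @return Character vector of probe sequences.
#' @export
probe_sequence <- function(designs, aptamer) {
  check_designs(designs, aptamer)
  vapply(seq_len(nrow(designs)), function(r) {
    i0 <- coord_to_index(designs$start5[r], aptamer)
    n <- designs$length[r]
    win <- strsplit(substring(aptamer$sequence, i0, i0 + n - 1L), "")[[1]]
    probe <- rev(complement_base(win)) # 5'->3' probe pairs window 3'->5'
    if (!is.na(designs$mismatch_pos[r])) {
      mm_idx <- coord_to_index(designs$mismatch_pos[r], aptamer)
      j <- (i0 + n - 1L) - mm_idx + 1L # probe position opposite the mismatch
      probe[j] <- mismatch_substitute(probe[j])
    }
    paste0(strrep("T", designs$linker5_len[r]), paste(probe, collapse = ""),
           strrep("T", designs$spacer3_len[r]))
  }, character(1))
}

check_designs <- function(designs, aptamer) {
  need <- c("start5", "length", "mismatch_pos")
  if (!all(need %in% names(designs))) {
    stop_violation("design table lacks columns: %s",
                   paste(setdiff(need, names(designs)), collapse = ", "))
  }
  i0 <- coord_to_index(designs$start5, aptamer)
  i1 <- i0 + designs$length - 1L
  if (any(designs$length < 1L)) stop_violation("ACE length must be >= 1")
  if (any(i1 > aptamer$length)) {
    stop_violation("duplex window extends past the aptamer 3' end")
  }
  has_mm <- !is.na(designs$mismatch_pos)
  if (any(has_mm)) {
    mi <- coord_to_index(designs$mismatch_pos[has_mm], aptamer)
    if (any(mi < i0[has_mm] | mi > i1[has_mm])) {
      stop_violation("mismatch position outside the duplex window")
    }
  }
  invisible(TRUE)
}

#' Canonical ACE names
#'
#' 5'-anchored form `5'_{N}{base}:{L}[:{MM}{base}]` where N is the aptamer
#' coordinate of the 5'-most duplexed base; the 3'-anchored form uses the
#' coordinate of the 3'-most duplexed base instead (skip-zero arithmetic, so
#' a 15-mer starting at -5 is anchored at +10). The mismatch suffix carries
#' the aptamer coordinate and aptamer base of the mismatched position.
#'
#' @param designs Design table rows.
#' @param aptamer The matching [aptamer_construct()].
#' @param anchor `"5p"` or `"3p"`.
#' @return Character vector of names, e.g. `"5'_1A:11"`, `"3'_11G:11"`,
#'   `"5'_4T:12:6G"`.
#' @export
format_name <- function(designs, aptamer, anchor = c("5p", "3p")) {
  anchor <- match.arg(anchor)
  check_designs(designs, aptamer)
  i0 <- coord_to_index(designs$start5, aptamer)
  if (anchor == "5p") {
    n <- designs$start5
  } else {
    n <- index_to_coord(i0 + designs$length - 1L, aptamer)
  }
  base <- aptamer_base(aptamer, n)
  suffix <- ifelse(is.na(designs$mismatch_pos), "",
                   paste0(":", designs$mismatch_pos,
                          aptamer_base(aptamer,
                                       ifelse(is.na(designs$mismatch_pos), 1L,
                                              designs$mismatch_pos))))
  paste0(if (anchor == "5p") "5'_" else "3'_", n, base, ":",
         designs$length, suffix)
}

#' Parse an ACE name
#'
#' Inverse of [format_name()]. Accepts both anchor conventions, ASCII `'` or
#' typographic prime characters, and an optional `Q` after the prime (used
#' for quencher-labelled solution constructs). Embedded base letters are
#' validated against the aptamer and disagreement is an error (it signals a
#' wrong aptamer or a corrupted name).
#'
#' @param names Character vector of ACE names.
#' @param aptamer The [aptamer_construct()] the names refer to.
#' @return Design table (canonical 5'-anchored rows).
#' @examples
#' parse_name("3'_11G:11", atp_dna_construct())[, c("start5", "length")]
#' @export
parse_name <- function(names, aptamer) {
  names <- chartr("ʹ′´", "'''", names)
  rx <- "^([53])'Q?_(-?[0-9]+)([ACGTU]):([0-9]+)(?::(-?[0-9]+)([ACGTU]))?$"
  m <- regmatches(names, regexec(rx, names))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop_violation("malformed ACE name: %s",
                   paste(names[bad], collapse = ", "))
  }
  f <- function(k) vapply(m, `[`, character(1), k + 1L)
  anchor <- f(1); n <- as.integer(f(2)); n_base <- f(3)
  len <- as.integer(f(4))
  mm <- suppressWarnings(as.integer(f(5))); mm_base <- f(6)
  idx_anchor <- coord_to_index(n, aptamer)
  i0 <- ifelse(anchor == "5", idx_anchor, idx_anchor - len + 1L)
  if (any(i0 < 1L)) stop_violation("window extends past the aptamer 5' end")
  start5 <- index_to_coord(i0, aptamer)
  ok <- aptamer_base(aptamer, n) == n_base
  if (any(!ok)) {
    stop_violation(
      "base letter disagrees with aptamer '%s' at coordinate %s (name %s)",
      aptamer$id, paste(n[!ok], collapse = ","),
      paste(names[!ok], collapse = ","))
  }
  has_mm <- !is.na(mm)
  if (any(has_mm)) {
    ok_mm <- aptamer_base(aptamer, mm[has_mm]) == mm_base[has_mm]
    if (any(!ok_mm)) {
      stop_violation("mismatch base letter disagrees with aptamer in: %s",
                     paste(names[has_mm][!ok_mm], collapse = ", "))
    }
  }
  d <- new_design_table(aptamer, start5, len, mm, 25L, 0L)
  check_designs(d, aptamer)
  d
}

#' Randomized identical sub-array layout
#'
#' Assigns `replicates` spots per design to grid positions; the seeded
#' random placement is generated once and replicated identically across all
#' sub-arrays (the fabrication convention for multi-condition slides).
#'
#' @param designs Design table.
#' @param n_subarrays Number of identical sub-arrays.
#' @param replicates Replicate spots per ACE per sub-array.
#' @param seed Integer seed controlling the placement permutation.
#' @param grid_dim Optional `c(rows, cols)`; default is the smallest
#'   square-ish grid holding all spots.
#' @return An `array_layout` list: `positions` (subarray_id, ace_id,
#'   replicate, grid_row, grid_col), `n_subarrays`, `replicates`,
#'   `grid_dim`, `seed`.
#' @export
assign_layout <- function(designs, n_subarrays, replicates, seed,
                          grid_dim = NULL) {
  if (nrow(designs) == 0L) stop_violation("no designs to lay out")
  if (replicates < 1L) stop_violation("replicates must be >= 1")
  n_spots <- nrow(designs) * as.integer(replicates)
  if (is.null(grid_dim)) {
    nc <- ceiling(sqrt(n_spots))
    grid_dim <- c(ceiling(n_spots / nc), nc)
  }
  capacity <- prod(grid_dim)
  if (n_spots > capacity) {
    stop_violation("sub-array capacity exceeded: need %d spots, grid %dx%d = %d",
                   n_spots, grid_dim[1], grid_dim[2], capacity)
  }
  cells <- with_seed(seed, sample.int(capacity, n_spots))
  one <- data.frame(
    ace_id = rep(designs$ace_id, each = replicates),
    replicate = rep(seq_len(replicates), times = nrow(designs)),
    grid_row = (cells - 1L) %/% grid_dim[2] + 1L,
    grid_col = (cells - 1L) %% grid_dim[2] + 1L,
    stringsAsFactors = FALSE)
  positions <- do.call(rbind, lapply(seq_len(n_subarrays), function(s) {
    cbind(subarray_id = sprintf("sa%d", s), one, stringsAsFactors = FALSE)
  }))
  rownames(positions) <- NULL
  structure(list(positions = positions, n_subarrays = as.integer(n_subarrays),
                 replicates = as.integer(replicates),
                 grid_dim = as.integer(grid_dim), seed = as.integer(seed)),
            class = "array_layout")
}

#' Write a probe manifest and FASTA
#'
#' Tab-separated manifest (both anchor names, coordinates, probe sequence,
#' flags) plus a FASTA of probe sequences keyed by the 5' name.
#'
#' @param designs Design table.
#' @param aptamer The matching [aptamer_construct()].
#' @param path Manifest TSV path.
#' @param fasta_path Optional FASTA path (default: `path` with `.fasta`).
#' @return The manifest data frame, invisibly.
#' @export
write_probe_manifest <- function(designs, aptamer, path,
                                 fasta_path = sub("\\.tsv$", ".fasta", path)) {
  man <- data.frame(
    ace_name_5p = designs$ace_id,
    ace_name_3p = format_name(designs, aptamer, "3p"),
    aptamer_id = designs$aptamer_id,
    start5 = designs$start5, length = designs$length,
    mismatch_pos = designs$mismatch_pos,
    probe_sequence = probe_sequence(designs, aptamer),
    flags = ifelse(designs$degenerate, "degenerate", ""),
    stringsAsFactors = FALSE)
  write_native_table(man, path, kind = "probes")
  seqs <- Biostrings::DNAStringSet(man$probe_sequence)
  names(seqs) <- man$ace_name_5p
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(man)
}
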