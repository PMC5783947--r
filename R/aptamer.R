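#' Aptamer construct with extension-aware coordinates
#'
#' An aptamer construct couples a 5'->3' sequence with the coordinate system
#' used throughout DA engineering: consensus base 1 is coordinate 1, bases of a
#' 5' extension are numbered ..., -2, -1, and there is no coordinate 0. All
#' window arithmetic in the package ("skip-zero" arithmetic) respects this, so
#' e.g. a 15-mer window starting at -5 ends at coordinate +10.
#'
#' @param id Construct identifier.
#' @param sequence 5'->3' base string, pure DNA (`ACGT`) or pure RNA (`ACGU`).
#' @param n5_extension Number of 5'-extension bases preceding consensus base 1.
#' @param description Free-text description.
#' @return An object of class `aptamer_construct` with elements `id`,
#'   `sequence`, `n5_extension`, `alphabet` ("DNA" or "RNA"), `length` and
#'   `description`.
#' @examples
#' apt <- aptamer_construct("toy", "CGATGACCT", n5_extension = 5)
#' aptamer_base(apt, c(-5, -1, 1, 4))
#' @export
aptamer_construct <- function(id, sequence, n5_extension = 0L,
                              description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) == 0L) {
    stop_violation("aptamer sequence must be non-empty")
  }
  chars <- strsplit(sequence, "")[[1]]
  is_dna <- all(chars %in% c("A", "C", "G", "T"))
  is_rna <- all(chars %in% c("A", "C", "G", "U"))
  if (!is_dna && !is_rna) {
    stop_violation("aptamer alphabet must be pure DNA {ACGT} or pure RNA {ACGU}")
  }
  n5_extension <- as.integer(n5_extension)
  if (n5_extension < 0L || n5_extension >= nchar(sequence)) {
    stop_violation("n5_extension must be in [0, length(sequence) - 1]")
  }
  structure(
    list(id = id, sequence = sequence, n5_extension = n5_extension,
         alphabet = if (is_dna) "DNA" else "RNA",
         length = nchar(sequence), description = description),
    class = "aptamer_construct")
}

#' @export
print.aptamer_construct <- function(x, ...) {
  cat(sprintf("<aptamer_construct> %s (%s, %d nt, 5' extension %d nt)\n",
              x$id, x$alphabet, x$length, x$n5_extension))
  cat(" 5'-", x$sequence, "-3'\n", sep = "")
  cat(sprintf(" coordinates %d..%d (no 0)\n",
              index_to_coord(1L, x), index_to_coord(x$length, x)))
  invisible(x)
}

# coordinate <-> string-index maps; both vectorized, both validate range
coord_to_index <- function(coord, aptamer) {
  coord <- as.integer(coord)
  if (any(coord == 0L, na.rm = TRUE)) {
    stop_violation("coordinate 0 does not exist")
  }
  ext <- aptamer$n5_extension
  idx <- ifelse(coord > 0L, coord + ext, coord + ext + 1L)
  bad <- !is.na(idx) & (idx < 1L | idx > aptamer$length)
  if (any(bad)) {
    stop_violation(sprintf("coordinate %s outside aptamer '%s'",
                           paste(coord[bad], collapse = ", "), aptamer$id))
  }
  idx
}

index_to_coord <- function(idx, aptamer) {
  idx <- as.integer(idx)
  ext <- aptamer$n5_extension
  ifelse(idx > ext, idx - ext, idx - ext - 1L)
}

#' Base at an aptamer coordinate
#'
#' @param aptamer An [aptamer_construct()].
#' @param coord Integer coordinate(s); negative values address the 5'
#'   extension, there is no coordinate 0.
#' @return Character vector of bases.
#' @export
aptamer_base <- function(aptamer, coord) {
  idx <- coord_to_index(coord, aptamer)
  substring(aptamer$sequence, idx, idx)
}

#' Classical ATP DNA aptamer construct
#'
#' The 27-nt ATP-binding DNA aptamer consensus with a 5-base 5' extension
#' (32 nt total), the construct used for the worked examples and simulator
#' presets in this package. Only extension bases -5 (C) and -2 (T) are fixed
#' by published DA construct names; the bases at -4, -3 and -1 are a synthetic
#' choice, so this is a partial reconstruction, not a verbatim published
#' sequence.
#'
#' @return An [aptamer_construct()].
#' @export
atp_dna_construct <- function() {
  aptamer_construct(
    id = "ATP_DNA",
    sequence = paste0("CGATG", "ACCTGGGGGAGTATTGCGGAGGAAGGT"),
    n5_extension = 5L,
    description = paste("ATP DNA aptamer consensus with 5-base 5' extension;",
                        "extension bases -4,-3,-1 are synthetic placeholders"))
}

# package-wide condition helpers -------------------------------------------

stop_violation <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("acekit_violation_error", "acekit_error")))
}

stop_io <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("acekit_io_error", "acekit_error")))
}

# run `expr` under a private RNG state seeded with `seed`; restores the
# caller's RNG so library code never perturbs user-level reproducibility
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
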