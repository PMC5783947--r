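#' @title Nearest-neighbor duplex thermodynamics
#' @description In-package nearest-neighbor (NN) estimates of ACE:aptamer
#'   duplex free energy and ACE self-structure free energy, used for the
#'   correlation analyses against hybridization and k_off landscapes and to
#'   drive the simulator's hybridization model. Perfect-match stacks use the
#'   unified DNA/DNA NN enthalpy/entropy set with duplex-initiation terms and
#'   the standard entropic monovalent-salt correction; divalent cations enter
#'   through a square-root monovalent-equivalence. Following the convention
#'   for light-directed DNA arrays, RNA-containing duplexes are modeled as
#'   DNA:DNA (a documented simplification that slightly depresses predicted
#'   stabilities for purine-rich RNA strands). Absolute agreement with
#'   partition-function web servers is not claimed; the module targets
#'   rank-order fidelity across a library.
#' @name thermo
NULL

# unified DNA/DNA NN parameters: dH kcal/mol, dS cal/(mol K), keyed by the
# 5'->3' top-strand dinucleotide; equivalent stacks (reverse complements)
# resolve to one entry
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
INIT_DH <- c(GC = 0.1, AT = 2.3) # per terminal base pair
INIT_DS <- c(GC = -2.8, AT = 4.1)

# fixed internal single-mismatch penalties (kcal/mol, replacing the two
# flanking perfect-match stacks): a deliberate simplification of the full
# mismatch NN tables, adequate for rank ordering across a library
MM_PENALTY <- c("A:A" = 0.61, "A:C" = 1.33, "A:G" = 0.14, "T:T" = 0.45)

revcomp_chr <- function(x) {
  paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit(x, "")[[1]]])), collapse = "")
}

nn_key <- function(dinuc) {
  rc <- vapply(dinuc, revcomp_chr, character(1))
  ifelse(dinuc %in% names(NN_DH), dinuc, rc)
}

stack_dH <- function(dinucs) sum(NN_DH[nn_key(dinucs)])
stack_dS <- function(dinucs) sum(NN_DS[nn_key(dinucs)])

#' Thermodynamic conditions
#'
#' @param temperature Celsius; NN parameters are extrapolated as
#'   temperature-independent dH/dS, adequate roughly between 0 and 70 C.
#' @param monovalent Monovalent cation concentration, molar.
#' @param divalent Divalent (Mg2+) concentration, molar; folded into an
#'   effective monovalent concentration as `mono + 0.120 * sqrt(div_mM)` M.
#' @return A `thermo_conditions` list.
#' @export
thermo_conditions <- function(temperature = 23, monovalent = 0.3,
                              divalent = 0.005) {
  if (monovalent < 0 || divalent < 0) stop_violation("salt must be >= 0")
  if (temperature < -10 || temperature > 90) {
    stop_violation("temperature outside NN validity range")
  }
  structure(list(temperature = temperature, monovalent = monovalent,
                 divalent = divalent),
            class = "thermo_conditions")
}

# effective monovalent (M): mono_M + 120 * sqrt(div_mM) mM
eff_na <- function(cond) {
  cond$monovalent + 0.120 * sqrt(cond$divalent * 1000)
}

duplex_dg_seq <- function(seq, cond, mismatch_win_pos = NA_integer_,
                          mismatch_pair = NA_character_) {
  n <- nchar(seq)
  if (n < 2L) stop_violation("duplex window shorter than 2: no stack defined")
  chars <- strsplit(seq, "")[[1]]
  dinucs <- paste0(chars[-n], chars[-1])
  keep <- rep(TRUE, n - 1L)
  penalty <- 0
  if (!is.na(mismatch_win_pos)) {
    # drop the stacks flanking the mismatched pair; internal mismatches add
    # a fixed identity-specific penalty, terminal ones only lose their stack
    p <- mismatch_win_pos
    keep[c(p - 1L, p)[c(p - 1L, p) >= 1L & c(p - 1L, p) <= n - 1L]] <- FALSE
    if (p > 1L && p < n) {
      pair <- paste(sort(strsplit(mismatch_pair, "")[[1]]), collapse = ":")
      penalty <- MM_PENALTY[pair]
      if (is.na(penalty)) penalty <- 1.0
    }
  }
  tK <- cond$temperature + 273.15
  dH <- stack_dH(dinucs[keep]) +
    sum(INIT_DH[ifelse(chars[c(1, n)] %in% c("G", "C"), "GC", "AT")])
  dS <- stack_dS(dinucs[keep]) +
    sum(INIT_DS[ifelse(chars[c(1, n)] %in% c("G", "C"), "GC", "AT")])
  # entropic salt correction, per phosphate-pair (length - 1), zero at 1 M
  dS <- dS + 0.368 * (n - 1) * log(eff_na(cond))
  unname(dH - tK * dS / 1000 + penalty)
}

#' Nearest-neighbor ACE:aptamer duplex free energy
#'
#' Stacking sum over the duplex window with initiation terms and salt
#' correction; single-mismatch designs lose the two stacks flanking the
#' mismatch and gain a fixed identity-specific penalty. Deterministic, and
#' translation-invariant: identical window sequences give identical values
#' wherever they sit in the aptamer.
#'
#' @param designs Design table rows.
#' @param aptamer The matching [aptamer_construct()].
#' @param cond A [thermo_conditions()] object.
#' @return Numeric vector, kcal/mol (more negative = more stable).
#' @export
duplex_dG <- function(designs, aptamer, cond = thermo_conditions()) {
  check_designs(designs, aptamer)
  vapply(seq_len(nrow(designs)), function(r) {
    i0 <- coord_to_index(designs$start5[r], aptamer)
    n <- designs$length[r]
    win <- substring(aptamer$sequence, i0, i0 + n - 1L)
    win_dna <- chartr("U", "T", win) # modeled as DNA:DNA
    if (is.na(designs$mismatch_pos[r])) {
      duplex_dg_seq(win_dna, cond)
    } else {
      mm_idx <- coord_to_index(designs$mismatch_pos[r], aptamer)
      apt_base <- chartr("U", "T", substring(aptamer$sequence, mm_idx, mm_idx))
      probe_base <- mismatch_substitute(complement_base(apt_base))
      duplex_dg_seq(win_dna, cond,
                    mismatch_win_pos = mm_idx - i0 + 1L,
                    mismatch_pair = paste0(apt_base, probe_base))
    }
  }, numeric(1))
}

#' ACE self-structure free energy
#'
#' Minimum free energy over an exhaustive search of hairpin candidates
#' (stem >= 3 bp, loop >= 3 nt, perfectly paired stems) and perfect
#' (ungapped, contiguously paired) self-dimers, with 0 as the no-structure
#' ceiling. A deliberate simplification of partition-function folding: it
#' ranks self-complementarity, it does not reproduce melting curves.
#'
#' @param sequence DNA sequence (probes are DNA).
#' @param cond A [thermo_conditions()] object.
#' @return Free energy in kcal/mol, always <= 0.
#' @examples
#' self_dG(strrep("T", 20)) # 0
#' @export
self_dG <- function(sequence, cond = thermo_conditions()) {
  seq <- chartr("U", "T", toupper(sequence))
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0
  tK <- cond$temperature + 273.15
  salt_ds_per_stack <- 0.368 * log(eff_na(cond))
  stack_g <- function(dinucs) {
    stack_dH(dinucs) - tK * (stack_dS(dinucs) +
                               salt_ds_per_stack * length(dinucs)) / 1000
  }
  # hairpins: stem pairs (i..i+s-1) with (j-s+1..j), loop j-s+1-i-s >= 3
  if (n >= 9L) {
    for (i in 1:(n - 8L)) {
      for (j in (i + 8L):n) {
        s_max <- min((j - i - 2L) %/% 2L, n)
        s <- 0L
        while (s < s_max && chars[i + s] == comp[chars[j - s]]) s <- s + 1L
        if (s >= 3L) {
          stem <- paste0(chars[i:(i + s - 2L)], chars[(i + 1L):(i + s - 1L)])
          loop_len <- (j - s + 1L) - (i + s - 1L) - 1L
          best <- min(best, stack_g(stem) + hairpin_loop_dg(loop_len, tK))
        }
      }
    }
  }
  # perfect self-dimers: antiparallel self-alignment at every offset; score
  # each contiguously complementary run of >= 4 pairs
  for (off in seq_len(2L * n - 1L)) {
    # pair chars[i] with chars[j], i + j = off + 1 .. constant per alignment
    i_range <- max(1L, off + 1L - n):min(n, off)
    run <- 0L; run_start <- NA_integer_
    for (i in i_range) {
      j <- off + 1L - i
      if (chars[i] == comp[chars[j]]) {
        if (run == 0L) run_start <- i
        run <- run + 1L
      }
      if ((chars[i] != comp[chars[j]] || i == max(i_range)) && run >= 4L) {
        idx <- run_start:(run_start + run - 1L)
        stem <- paste0(chars[idx[-length(idx)]], chars[idx[-1L]])
        ends <- chars[c(idx[1], idx[length(idx)])]
        init <- sum(INIT_DH[ifelse(ends %in% c("G", "C"), "GC", "AT")]) -
          tK * sum(INIT_DS[ifelse(ends %in% c("G", "C"), "GC", "AT")]) / 1000
        best <- min(best, stack_g(stem) + init)
        run <- 0L
      }
      if (chars[i] != comp[chars[j]]) run <- 0L
    }
  }
  best
}

# DNA hairpin loop initiation penalties (kcal/mol at 37 C, used as
# temperature-independent dG); Jacobson-Stockmayer extrapolation beyond 10
hairpin_loop_dg <- function(len, tK) {
  tab <- c(`3` = 3.5, `4` = 3.5, `5` = 3.3, `6` = 4.0, `7` = 4.2, `8` = 4.3,
           `9` = 4.5, `10` = 4.4)
  if (len <= 10L) tab[as.character(max(len, 3L))]
  else tab["10"] + 1.75 * 0.0019872 * tK * log(len / 10)
}

#' Correlate a landscape against a predictor vector
#'
#' Pairwise-complete Pearson and Spearman correlations between per-ACE
#' landscape values and a per-ACE predictor (e.g. duplex free energy).
#'
#' @param values,predictor Aligned numeric vectors.
#' @return List `r_pearson`, `rho_spearman`, `n`, `flag` (`"undefined"`
#'   when fewer than 3 complete pairs).
#' @export
landscape_correlation <- function(values, predictor) {
  ok <- !is.na(values) & !is.na(predictor)
  n <- sum(ok)
  if (n < 3L) {
    return(list(r_pearson = NA_real_, rho_spearman = NA_real_, n = n,
                flag = "undefined"))
  }
  list(r_pearson = stats::cor(values[ok], predictor[ok]),
       rho_spearman = stats::cor(values[ok], predictor[ok],
                                 method = "spearman"),
       n = n, flag = "")
}
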