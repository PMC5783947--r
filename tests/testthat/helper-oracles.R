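# Independent oracles and small fixtures shared across test files.

# a 12-nt DNA construct with a 3-base 5' extension: coordinates -3..9
toy_aptamer <- function() {
  aptamer_construct("toy", "GCTACGTAGGAT", n5_extension = 3L)
}

toy_rna <- function() {
  aptamer_construct("toyRNA", "GGAUCCGUA", n5_extension = 0L)
}

# brute-force design counting: enumerate every (window, [position]) tuple
# explicitly on a dummy string of length L, then count
brute_pm_count <- function(L, X, Y) {
  n <- 0L
  for (len in X:Y) n <- n + length(seq_len(L - len + 1L))
  n
}

brute_mm_count <- function(L, X, Y) {
  n <- 0L
  for (len in X:Y) {
    for (i0 in seq_len(L - len + 1L)) n <- n + length(seq_len(len))
  }
  n
}

# grid-search oracle for the Michaelis-Menten dose-response fit
grid_fit_oracle <- function(conc, k, n_grid = 200) {
  kmax_grid <- seq(1e-3, 2 * max(k), length.out = n_grid)
  K_grid <- exp(seq(log(min(conc) / 10), log(max(conc) * 10),
                    length.out = n_grid))
  best <- c(rss = Inf, kmax = NA, K = NA)
  for (km in kmax_grid) {
    pred <- outer(K_grid, conc, function(K, c) km * c / (K + c))
    rss <- rowSums((pred - matrix(k, n_grid, length(k), byrow = TRUE))^2)
    j <- which.min(rss)
    if (rss[j] < best["rss"]) best <- c(rss = rss[j], kmax = km, K = K_grid[j])
  }
  best
}

# a tiny noiseless simulated dataset used by several files
noiseless_dataset <- function(seed = 7) {
  sc <- make_scenario("atp_dna_like", seed = seed, noise_sigma = 0,
                      failure_morphology = 0, failure_background = 0)
  list(scenario = sc, data = simulate_slide(sc))
}

# build a minimal valid spot table by hand
make_spots <- function(n, subarray = "sa1", slide = "slide1",
                       round = "post_hyb", channel = "green",
                       signal = 1000, pixel_sd = 80, background = 50,
                       ace = NULL) {
  data.frame(
    subarray_id = subarray, slide_id = slide,
    ace_id = if (is.null(ace)) sprintf("ace%03d", seq_len(n)) else ace,
    replicate = if (is.null(ace)) rep(1L, n) else
      stats::ave(seq_len(n), ace, FUN = seq_along),
    round = round, channel = channel,
    median_signal = rep_len(signal, n), pixel_sd = rep_len(pixel_sd, n),
    background_mean = rep_len(background, n),
    grid_row = seq_len(n), grid_col = 1L,
    stringsAsFactors = FALSE)
}
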