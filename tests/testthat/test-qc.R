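test_that("low-signal rule is strict at the 200 RFU boundary", {
  expect_identical(flag_low_signal(c(199.9, 200, 5000)),
                   c(TRUE, FALSE, FALSE))
  expect_identical(flag_low_signal(150, threshold = 100), FALSE)
})

test_that("morphology rule flags exactly the planted CV outlier", {
  n <- 1000
  sig <- rep(1000, n)
  sd_px <- rep(100, n) # CV = 0.10
  sd_px[17] <- 900     # CV = 0.90
  flags <- flag_morphology(sig, sd_px)
  # direct mean + 3 sd computation on the fixture
  cv <- sd_px / sig
  cut <- mean(cv) + 3 * stats::sd(cv)
  expect_identical(flags, cv > cut)
  expect_identical(which(flags), 17L)
  # identical CVs: sd = 0, strict inequality, none flagged
  expect_false(any(flag_morphology(rep(500, 10), rep(50, 10))))
  # scale invariance: CV is scale-free
  expect_identical(flag_morphology(sig * 7.3, sd_px * 7.3), flags)
  expect_error(flag_morphology(c(0, 1), c(1, 1)),
               class = "acekit_violation_error")
})

test_that("background rule flags spots beyond mean + 3 sd, coincident outliers included", {
  bg <- c(rep(50, 99), 50)
  expect_false(any(flag_background(bg))) # uniform, sd = 0
  withr::local_seed(42)
  bg2 <- rnorm(200, 50, 5)
  bg2[7] <- mean(bg2[-7]) + 4 * stats::sd(bg2[-7]) * 3 # far outlier
  f <- flag_background(bg2)
  expect_identical(f, bg2 > mean(bg2) + 3 * stats::sd(bg2))
  expect_true(f[7])
  # two coincident outliers: both flagged iff each exceeds the cutoff that
  # includes both
  bg3 <- c(rep(10, 500), 100, 100)
  cut3 <- mean(bg3) + 3 * stats::sd(bg3)
  expect_identical(flag_background(bg3), bg3 > cut3)
  # uniform rescaling does not change flags
  expect_identical(flag_background(bg2 * 3), f)
})

test_that("replicate aggregation applies the <3-passing exclusion dataset-wide", {
  # ACE 'a': 5 replicates, 2 flagged low -> n_pass 3, retained with the
  # mean of the passing replicates; ACE 'b': 3 of 5 flagged in sa1 ->
  # excluded everywhere, including in clean sa2
  mk <- function(subarray, ace, sig) {
    s <- make_spots(length(sig), subarray = subarray, ace = rep(ace,
                                                                length(sig)))
    s$median_signal <- sig
    s$grid_row <- seq_along(sig) + ifelse(ace == "b", 100L, 0L)
    s
  }
  spots <- rbind(
    mk("sa1", "a", c(100, 150, 1000, 2000, 3000)),
    mk("sa1", "b", c(100, 120, 140, 5000, 6000)),
    mk("sa2", "a", c(900, 1000, 1100, 1200, 1300)),
    mk("sa2", "b", c(900, 1000, 1100, 1200, 1300)))
  post <- spots
  post$round <- "post_incubation"
  post$median_signal <- post$median_signal * 0.5
  q <- qc_spots(rbind(spots, post))
  m <- q$measurements
  a1 <- m[m$ace_id == "a" & m$subarray_id == "sa1" & m$round == "post_hyb", ]
  expect_equal(a1$n_pass, 3)
  expect_false(a1$excluded)
  expect_equal(a1$mean_signal, mean(c(1000, 2000, 3000)))
  b <- m[m$ace_id == "b", ]
  expect_true(all(b$excluded))
  expect_true(all(is.na(b$mean_signal)))
  # flagged post-hyb spots are excluded from the post-incubation round too
  a1p <- m[m$ace_id == "a" & m$subarray_id == "sa1" &
             m$round == "post_incubation", ]
  expect_equal(a1p$mean_signal, mean(c(500, 1000, 1500)))

  # raising min_pass never un-excludes an ACE
  excl <- function(mp) {
    mm <- qc_spots(rbind(spots, post), min_pass = mp)$measurements
    sort(unique(mm$ace_id[mm$excluded]))
  }
  e3 <- excl(3); e4 <- excl(4); e5 <- excl(5)
  expect_true(all(e3 %in% e4))
  expect_true(all(e4 %in% e5))
})

test_that("flags are invariant to spot order", {
  spots <- make_spots(50)
  spots$median_signal <- 300 + seq_len(50) * 10
  spots$pixel_sd <- spots$median_signal * 0.1
  spots$pixel_sd[25] <- spots$median_signal[25] # CV outlier
  q1 <- qc_spots(spots)$flags
  withr::local_seed(99)
  perm <- sample(nrow(spots))
  q2 <- qc_spots(spots[perm, ])$flags
  key <- function(f) f[order(f$ace_id, f$replicate), c("ace_id", "pass")]
  expect_equal(key(q1), key(q2), ignore_attr = TRUE)
})

test_that("planted simulator failures are recovered by the flag rules", {
  sc <- make_scenario("flat_null", seed = 5, noise_sigma = 0.05,
                      failure_morphology = 0.002, failure_background = 0.002)
  ds <- simulate_slide(sc)
  q <- qc_spots(ds$spots)
  hyb <- ds$spots[ds$spots$round == "post_hyb" &
                    ds$spots$channel == "green", ]
  key <- function(d) paste(d$slide_id, d$subarray_id, d$ace_id, d$replicate)
  planted_morph <- key(hyb[hyb$planted_morphology, ])
  planted_bg <- key(hyb[hyb$planted_background, ])
  flagged_morph <- key(q$flags[q$flags$bad_morphology, ])
  flagged_bg <- key(q$flags[q$flags$high_background, ])
  # 10x inflations exceed the mean + 3 sd cutoffs by construction
  expect_setequal(flagged_morph, planted_morph)
  expect_setequal(flagged_bg, planted_bg)
  # planted rate ~0.2%: recovered count within binomial error
  n <- nrow(hyb)
  expect_lt(abs(length(planted_morph) - 0.002 * n),
            4 * sqrt(n * 0.002 * 0.998) + 1)
})
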