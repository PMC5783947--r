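test_that("calibration identities hold exactly", {
  # the Calibration condition normalizes to exactly 100%
  expect_equal(relative_loss(1000, 960, 1000, 960), 100)
  expect_equal(relative_loss(500, 420, 1000, 960), 100 * 80 / 40)
  # cond loss 80, cal loss 40 -> 200%
  expect_equal(relative_loss(1000, 920, 1000, 960), 200)
  # zero calibration loss is uncalibratable
  expect_true(is.na(relative_loss(1000, 900, 1000, 1000)))

  # condition losing exactly the calibration fraction -> survival 1, k = 0
  cs <- corrected_survival(1000, 800, phi = 0.2)
  expect_equal(cs$survival, 1)
  expect_false(cs$clipped)
  expect_equal(rate_from_survival(cs$survival, 1), 0)
  # phi = 0.2, F_hyb 1000, F_post 400 -> S = 0.5
  expect_equal(corrected_survival(1000, 400, 0.2)$survival, 0.5)
  # gains above the calibration expectation clip to 1 with a flag
  cs2 <- corrected_survival(1000, 900, 0.2)
  expect_equal(cs2$survival, 1)
  expect_true(cs2$clipped)
  expect_true(corrected_survival(1000, 100, 1.0)$uncalibratable)

  # closed-form rates
  expect_equal(rate_from_survival(exp(-1), 1), 1)
  expect_equal(rate_from_survival(0.5, 1), log(2))
  expect_equal(rate_from_survival(0.5, 2), log(2) / 2)
  expect_error(rate_from_survival(0, 1), class = "acekit_violation_error")
  expect_error(rate_from_survival(0.5, 0), class = "acekit_violation_error")

  # induced-fit additivity
  expect_equal(induced_fit_rate(1.2, 0.2)$k_star, 1.0)
  expect_equal(induced_fit_rate(0.2, 0.2)$k_star, 0)
  neg <- induced_fit_rate(0.1, 0.2)
  expect_equal(neg$k_star, -0.1)
  expect_equal(neg$k_star_floored, 0)
  expect_true(neg$floored)
})

test_that("larger relative loss always means smaller corrected survival", {
  F_hyb <- 1000
  losses <- seq(150, 600, by = 50) # above the 10% calibration loss: no clip
  rl <- relative_loss(F_hyb, F_hyb - losses, 1000, 900)
  cs <- corrected_survival(F_hyb, F_hyb - losses, 0.1)$survival
  expect_true(all(diff(rl) > 0))
  expect_true(all(diff(cs) < 0))
})

test_that("noiseless dose-response points are recovered to machine-level accuracy", {
  conc <- dilution_series(0.124e-6, 10e-3, 8)
  truth <- list(K = 200e-6, kmax = 1.0)
  k <- truth$kmax * conc / (truth$K + conc)
  f <- fit_dose_response(conc, k)
  expect_true(f$converged)
  expect_lt(abs(f$K_fit - truth$K) / truth$K, 1e-6)
  expect_lt(abs(f$k_star_max - truth$kmax) / truth$kmax, 1e-6)
  # half-saturation identity: predicted k* at [L] = K_fit is k*_max / 2
  expect_equal(f$k_star_max * truth$K / (f$K_fit + truth$K),
               truth$kmax / 2, tolerance = 1e-6)
  # all-zero responses: k*_max = 0, K undefined-flagged
  z <- fit_dose_response(conc, rep(0, 8))
  expect_equal(z$k_star_max, 0)
  expect_true(is.na(z$K_fit))
  expect_equal(z$flag, "all_zero")
  expect_error(fit_dose_response(c(1e-6, 1e-6), c(1, 1)),
               class = "acekit_violation_error")
})

test_that("Michaelis-Menten predictions increase in [L] and are bounded by k*_max", {
  conc <- dilution_series(1e-8, 1e-2, 30)
  for (pars in list(c(1e-5, 0.4), c(2e-4, 1.0), c(1e-3, 0.05))) {
    pred <- pars[2] * conc / (pars[1] + conc)
    expect_true(all(diff(pred) > 0))
    expect_true(all(pred < pars[2]))
  }
})

test_that("the LM fit agrees with a grid-search oracle under noise", {
  conc <- dilution_series(0.124e-6, 10e-3, 8)
  withr::local_seed(31)
  for (i in 1:3) {
    k <- 0.8 * conc / (3e-4 + conc) * rlnorm(8, 0, 0.1)
    f <- fit_dose_response(conc, k)
    o <- grid_fit_oracle(conc, k)
    # LM must do at least as well as the grid optimum, parameters close
    expect_lte(f$rss, o["rss"] * 1.001)
    expect_lt(abs(log(f$K_fit / o["K"])), log(1.3))
    expect_lt(abs(f$k_star_max - o["kmax"]) / o["kmax"], 0.15)
  }
})

test_that("the fit is invariant to concentration unit rescaling", {
  conc <- dilution_series(0.124e-6, 10e-3, 8)
  withr::local_seed(13)
  k <- 1.0 * conc / (2e-4 + conc) * rlnorm(8, 0, 0.05)
  f1 <- fit_dose_response(conc, k)
  f2 <- fit_dose_response(conc * 1e6, k) # molar -> micromolar
  expect_equal(f2$K_fit, f1$K_fit * 1e6, tolerance = 1e-6)
  expect_equal(f2$k_star_max, f1$k_star_max, tolerance = 1e-8)
  expect_equal(f2$rss, f1$rss, tolerance = 1e-8)
})

test_that("estimate_rates reproduces hand-computed values on a tiny fixture", {
  # one ACE, one slide: Calibration loses 10%, BufferOnly survival 0.8,
  # Ligand survival 0.5 (after handling correction)
  mk <- function(sa, rnd, F) {
    data.frame(ace_id = "a", subarray_id = sa, slide_id = "slide1",
               round = rnd, channel = "green", mean_signal = F,
               sd_signal = 0, n_pass = 5L, excluded = FALSE,
               stringsAsFactors = FALSE)
  }
  m <- rbind(mk("sa1", "post_hyb", 1000), mk("sa1", "post_incubation", 900),
             mk("sa2", "post_hyb", 1000), mk("sa2", "post_incubation", 720),
             mk("sa3", "post_hyb", 1000), mk("sa3", "post_incubation", 450))
  cond <- data.frame(
    subarray_id = c("sa1", "sa2", "sa3"), slide_id = "slide1",
    condition = c("Calibration", "BufferOnly", "Ligand"),
    ligand_name = c("", "", "ATP"), concentration = c(0, 0, 1e-3),
    temperature = 23, delta_t = 1, buffer_label = "b",
    stringsAsFactors = FALSE)
  rr <- estimate_rates(m, cond)
  expect_equal(rr$rates$k_off, -log(0.8))
  expect_equal(rr$dose$k_star, -log(0.5) + log(0.8))
  cal <- rr$calibrated
  expect_equal(cal$relative_loss[cal$condition == "BufferOnly"],
               100 * 280 / 100)
  expect_equal(cal$relative_loss[cal$condition == "Ligand"], 100 * 550 / 100)
})
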