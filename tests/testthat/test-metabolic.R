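make_plateau_trace <- function(levels, n_per = 3) {
  n <- 4 * n_per
  times <- 6.5 * seq_len(n)
  inj <- times[n_per * (1:3)] + 3.25
  names(inj) <- c("oligomycin", "fccp", "rotenone_antimycin")
  flux_trace(times, rep(levels, each = n_per), inj)
}

test_that("respiration parameters follow the stress-test arithmetic", {
  rp <- respiration_params(make_plateau_trace(c(100, 40, 150, 10)))
  expect_equal(rp$non_mito, 10)
  expect_equal(rp$basal, 90)
  expect_equal(rp$atp_linked, 60)
  expect_equal(rp$proton_leak, 30)
  expect_equal(rp$maximal, 140)
  expect_equal(rp$reserve, 50)

  flat <- respiration_params(make_plateau_trace(rep(55, 4)))
  expect_equal(c(flat$basal, flat$maximal, flat$reserve), c(0, 0, 0))

  # missing injection is named
  tr <- make_plateau_trace(c(100, 40, 150, 10))
  names(tr$injections)[2] <- "uncoupler"
  expect_error(respiration_params(tr), "fccp")

  # negative reserve is flagged, not silently dropped
  expect_warning(rp_neg <- respiration_params(make_plateau_trace(c(150, 40, 100, 10))),
                 "reserve")
  expect_equal(rp_neg$reserve, -50)
})

test_that("respiration additivity identities hold on noisy traces", {
  for (seed in 1:10) {
    truth <- respiration_truth(10, 90, 60, 140)
    rp <- respiration_params(simulate_ocr_trace(truth, noise_sd = 5, seed = seed))
    expect_equal(rp$basal, rp$atp_linked + rp$proton_leak)
    expect_equal(rp$reserve, rp$maximal - rp$basal)
  }
})

test_that("baseline convention 'first' uses the first measurement", {
  tr <- make_plateau_trace(c(100, 40, 150, 10))
  tr$values[1] <- 110
  expect_equal(respiration_params(tr, baseline = "first")$basal, 100)
  expect_equal(respiration_params(tr, baseline = "mean")$basal,
               mean(c(110, 100, 100)) - 10)
})

test_that("ECAR min/max are the extreme segment means", {
  expect_equal(ecar_minmax(make_plateau_trace(c(20, 35, 27, 22))),
               c(minimal = 20, maximal = 35))
  const <- flux_trace(1:6, rep(7, 6))
  expect_equal(ecar_minmax(const), c(minimal = 7, maximal = 7))
  # brute force over segment means
  tr <- simulate_ocr_trace(respiration_truth(10, 90, 60, 140), 3, seed = 2)
  brute <- range(tapply(tr$values, tr$segment, mean))
  expect_equal(unname(ecar_minmax(tr)), brute)
})

test_that("4PL fitting recovers noiseless parameters and flags flat data", {
  dr <- simulate_dose_response(2.0, hill = 1.8, floor = 0.08, noise_sd = 0, seed = 1)
  fit <- fit_4pl(dr)
  expect_equal(fit$ic50, 2.0, tolerance = 1e-6)
  expect_equal(fit$hill, 1.8, tolerance = 1e-5)
  expect_equal(fit$bottom, 0.08, tolerance = 1e-5)

  # scale equivariance: doses in nM recover 1000x the IC50
  dr_nm <- dr; dr_nm$dose <- dr_nm$dose * 1000
  expect_equal(fit_4pl(dr_nm)$ic50 / fit$ic50, 1000, tolerance = 1e-5)

  flat <- data.frame(dose = rep(0:4, 2), viability = 1)
  expect_warning(f_flat <- fit_4pl(flat), "unidentifiable")
  expect_false(f_flat$identifiable)
  expect_true(is.na(f_flat$ic50))

  expect_error(fit_4pl(data.frame(dose = c(0, 1, 1, 2), viability = 1:4)),
               "4 distinct doses")
})

test_that("percent change follows the direction convention with exact MW p", {
  pc <- percent_change(c(100, 100, 100), c(42, 42, 42), "decrease")
  expect_equal(pc$percent, 58)

  same <- percent_change(c(1, 2, 3), c(1, 2, 3), "increase")
  expect_equal(same$percent, 0)
  expect_equal(same$p, 1)

  # U statistic and exact p match full enumeration at n = 3 vs 3
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3, 0.5)
    got <- percent_change(x, y, "increase")
    oracle <- oracle_mannwhitney(y, x)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p, oracle$p)
  }

  # control vs itself is always 0%
  for (i in 1:5) {
    x <- rlnorm(5)
    expect_equal(percent_change(x, x, "decrease")$percent, 0)
  }

  expect_error(percent_change(c(0, 0, 0), c(1, 1, 1)), "zero")
  expect_error(percent_change(c(1, 2), c(1, 2, 3)), "3 replicates")
})

test_that("glucose uptake per cell is the count-normalized luminescence", {
  g <- glucose_uptake_per_cell(c(1000, 1200), c(100, 120))
  expect_equal(g$per_cell, c(10, 10))
  # scale invariance
  g2 <- glucose_uptake_per_cell(c(2000, 2400), c(200, 240))
  expect_equal(g2$per_cell, g$per_cell)
  # brute force on random tables
  set.seed(7)
  lum <- runif(6, 500, 1500); cells <- runif(6, 50, 150)
  expect_equal(glucose_uptake_per_cell(lum, cells)$per_cell, lum / cells)
  expect_error(glucose_uptake_per_cell(1000, 0), "positive")
})
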