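test_that("lambda grids are even and window runs are seed-deterministic", {
  hd <- make_harmonic_diabat_system()
  w2 <- run_evb_windows(hd$topology, hd$conformation, n_windows = 2,
                        steps_per_window = 50, seed = 1,
                        frozen_atoms = hd$frozen)
  expect_equal(sort(unique(window_lambdas(w2))), c(0, 1))
  w51 <- seq(0, 1, length.out = 51)
  expect_true(0.5 %in% w51)
  expect_equal(unique(round(diff(w51), 10)), 0.02)
  wa <- run_evb_windows(hd$topology, hd$conformation, n_windows = 5,
                        steps_per_window = 100, seed = 9,
                        frozen_atoms = hd$frozen)
  wb <- run_evb_windows(hd$topology, hd$conformation, n_windows = 5,
                        steps_per_window = 100, seed = 9,
                        frozen_atoms = hd$frozen)
  expect_identical(lapply(wa, `[[`, "e1"), lapply(wb, `[[`, "e1"))
  expect_error(run_evb_windows(hd$topology, hd$conformation, n_windows = 1),
               "at least two")
})

test_that("window samples satisfy the mapping-energy identity", {
  hd <- make_harmonic_diabat_system()
  ws <- run_evb_windows(hd$topology, hd$conformation, n_windows = 5,
                        steps_per_window = 200, seed = 3,
                        frozen_atoms = hd$frozen)
  for (w in ws) {
    expect_true(all(abs(w$e_map - ((1 - w$lambda) * w$e1 + w$lambda * w$e2))
                    < 1e-9))
  }
})

test_that("FEP estimator reproduces closed forms", {
  # identical states: zero everywhere
  w <- lapply(seq(0, 1, 0.25), function(l)
    fake_window(l, e1 = rnorm(200), e2 = NULL))
  for (i in seq_along(w)) w[[i]]$e2 <- w[[i]]$e1
  fep <- fep_cumulative(w, 300)
  expect_equal(max(abs(fep$dG_lambda)), 0, tolerance = 1e-12)

  # constant perturbation e2 = e1 + c gives dG = c exactly
  w <- lapply(c(0, 1), function(l) {
    e1 <- rnorm(100)
    fake_window(l, e1 = e1, e2 = e1 + 4.2)
  })
  fep <- fep_cumulative(w, 300)
  expect_equal(fep$dG_lambda[2], 4.2, tolerance = 1e-10)
  expect_equal(max(abs(fep$hysteresis)), 0, tolerance = 1e-10)

  # Gaussian perturbation: dG = mu - beta sigma^2 / 2. In the endpoint
  # ensembles of a Gaussian linear-response model the gap is normal with
  # the same variance but its mean is shifted by -beta sigma^2 in the
  # product ensemble.
  kT <- physical_constants$kB_kcal * 300
  mu <- 1.3; sigma <- 0.6
  set.seed(5)
  n <- 20000
  mk <- function(l, mean_gap) {
    e1 <- rnorm(n, 0, 0.1)
    fake_window(l, e1 = e1, e2 = e1 + rnorm(n, mean_gap, sigma))
  }
  fep <- fep_cumulative(list(mk(0, mu), mk(1, mu - sigma^2 / kT)), 300)
  expected <- mu - sigma^2 / (2 * kT)
  # Monte-Carlo error of the exponential average, delta method
  se <- kT * sqrt((exp(sigma^2 / kT^2) - 1) / n)
  expect_lt(abs(fep$dG_lambda[2] - expected), 3 * se)
  expect_error(fep_cumulative(list(), 300), "no windows")
})

test_that("gap profile is flat for identical states and symmetric for a symmetric toy", {
  set.seed(6)
  w <- lapply(seq(0, 1, 0.5), function(l) {
    e1 <- rnorm(2000, 0, 1)
    fake_window(l, e1 = e1, e2 = e1)
  })
  prof <- gap_profile(w, temperature = 300, n_bins = 12, min_samples = 5)
  g <- prof$g[!is.na(prof$g)]
  expect_lt(max(g) - min(g), 1e-9)

  # symmetric harmonic diabats, alpha = 0: dG0 ~ 0 and mirror-symmetric wells
  hd <- make_harmonic_diabat_system(k1 = 4, k2 = 4, r1 = 2.5, r2 = 3.5,
                                    alpha = 0, h12 = 0.3)
  fe <- evb_free_energy(hd$topology, hd$conformation, n_windows = 11,
                        steps_per_window = 3000, n_replicates = 3, seed = 17,
                        frozen_atoms = hd$frozen, n_bins = 30,
                        min_samples = 10)
  expect_lt(abs(fe$barriers$dG_rxn), 0.35)
})

test_that("profile matches direct Boltzmann quadrature on a 1D two-state toy", {
  k <- 3; r1 <- 2; r2 <- 4; h12 <- 0.5
  hd <- make_harmonic_diabat_system(k1 = k, k2 = k, r1 = r1, r2 = r2,
                                    alpha = 0, h12 = h12)
  ws <- run_evb_windows(hd$topology, hd$conformation, n_windows = 11,
                        steps_per_window = 100000, seed = 11, n_replicates = 3,
                        frozen_atoms = hd$frozen, sample_every = 20)
  prof <- gap_profile(ws, temperature = 300, n_bins = 40, min_samples = 60)
  kT <- physical_constants$kB_kcal * 300
  # oracle: radial quadrature of the ground-state Boltzmann weight (the
  # mobile particle lives in 3D, so the Jacobian is r^2)
  eg <- function(r) {
    e1 <- k * (r - r1)^2; e2 <- k * (r - r2)^2
    0.5 * (e1 + e2) - 0.5 * sqrt((e1 - e2)^2 + 4 * h12^2)
  }
  r <- seq(0.5, 6.5, length.out = 200001)
  w <- r^2 * exp(-(eg(r) - min(eg(r))) / kT)
  x <- k * (r - r1)^2 - k * (r - r2)^2
  half <- diff(prof$gap_bins[1:2]) / 2
  edges <- c(prof$gap_bins - half, max(prof$gap_bins) + half)
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  pb <- tapply(w, factor(b, levels = seq_along(prof$gap_bins)), sum)
  gq <- -kT * log(as.numeric(pb))
  keep <- !is.na(prof$g) & is.finite(gq)
  dev <- prof$g[keep] - gq[keep]
  dev <- dev - mean(dev)          # profiles agree up to an additive constant
  expect_gt(sum(keep), 15)
  expect_lt(max(abs(dev)), 0.3)
})

test_that("barrier extraction finds tabulated extrema and rejects monotone profiles", {
  mkprof <- function(g, x = seq(-10, 10, length.out = length(g)))
    structure(list(gap_bins = x, g = g - min(g),
                   samples_per_bin = rep(100, length(g)),
                   dG_lambda = NULL, temperature = 300),
              class = "free_energy_profile")
  # double well with known extrema: minima 0 and 2, barrier 6 at x ~ 0
  x <- seq(-10, 10, length.out = 81)
  g <- ifelse(x < 0, 6 * (1 - (x / 10 + 0.5)^2 / 0.25),
              2 + 4 * (1 - (x / 10 - 0.5)^2 / 0.25))
  g[abs(x) < 0.125] <- 6
  br <- suppressWarnings(extract_barriers(mkprof(g, x)))
  expect_equal(br$dG_act, 6, tolerance = 1e-9)
  expect_equal(br$dG_rxn, 2, tolerance = 1e-9)
  expect_equal(br$n_replicates, 1)
  expect_equal(br$sem_act, 0)

  # symmetric double well: dG0 = 0
  gs <- (x^2 - 25)^2 / 100
  br <- suppressWarnings(extract_barriers(mkprof(gs, x)))
  expect_equal(br$dG_rxn, 0, tolerance = 1e-9)

  expect_error(extract_barriers(mkprof(seq(0, 5, length.out = 40))),
               "no barrier")

  # replicate statistics: mean and sem over two tabulated replicates
  g2 <- g; g2[abs(x) < 0.125] <- 7
  br <- extract_barriers(list(mkprof(g, x), mkprof(g2, x)))
  expect_equal(br$dG_act, 6.5, tolerance = 1e-9)
  expect_equal(br$sem_act, sd(c(6, 7)) / sqrt(2), tolerance = 1e-9)
})

test_that("reorganization energy matches the harmonic closed form", {
  # e1 identical to e2: zero
  w <- lapply(c(0, 1), function(l) {
    e1 <- rnorm(500)
    fake_window(l, e1 = e1, e2 = e1)
  })
  expect_equal(reorganization_energy(w), 0, tolerance = 1e-12)
  expect_error(reorganization_energy(w[1]), "endpoint")

  # harmonic diabats, equal k: lambda_R = k d^2 (k d^2 energy convention)
  k <- 3; d <- 2
  hd <- make_harmonic_diabat_system(k1 = k, k2 = k, r1 = 2, r2 = 2 + d,
                                    alpha = 0, h12 = 0.2)
  ws <- run_evb_windows(hd$topology, hd$conformation, n_windows = 5,
                        steps_per_window = 8000, seed = 19, n_replicates = 3,
                        frozen_atoms = hd$frozen)
  lr <- reorganization_energy(ws)
  expect_lt(abs(lr - k * d^2) / (k * d^2), 0.12)
  # swapping the state labels leaves lambda_R unchanged
  ws_sw <- lapply(ws, function(w) {
    w2 <- w
    w2$lambda <- 1 - w$lambda
    w2$e1 <- w$e2; w2$e2 <- w$e1; w2$gap <- -w$gap
    w2
  })
  expect_equal(reorganization_energy(ws_sw), lr, tolerance = 1e-12)
})

test_that("Marcus relation holds for harmonic diabats with small coupling", {
  hd <- make_harmonic_diabat_system(k1 = 3, k2 = 3, r1 = 2, r2 = 4,
                                    alpha = 0, h12 = 0.5)
  fe <- evb_free_energy(hd$topology, hd$conformation, n_windows = 11,
                        steps_per_window = 40000, n_replicates = 3, seed = 23,
                        frozen_atoms = hd$frozen, n_bins = 40,
                        min_samples = 20, sample_every = 20)
  lr <- reorganization_energy(fe$windows)
  marcus <- (lr + fe$barriers$dG_rxn)^2 / (4 * lr) - hd$topology$h12
  expect_lt(abs(fe$barriers$dG_act - marcus), 0.5)
})

test_that("calibration recovers planted barrier targets and rejects infeasible ones", {
  hd <- make_harmonic_diabat_system(k1 = 3, k2 = 3, r1 = 2, r2 = 4,
                                    alpha = -2, h12 = 0.8)
  base <- list(topology = hd$topology, start_conformation = hd$conformation,
               frozen_atoms = hd$frozen, steps_per_window = 3000, seed = 31)
  # targets computed at the planted parameters
  fe <- suppressWarnings(
    evb_free_energy(hd$topology, hd$conformation, n_windows = 11,
                    steps_per_window = 3000, n_replicates = 1, seed = 31,
                    frozen_atoms = hd$frozen, n_bins = 40, min_samples = 5))
  tact <- fe$barriers$dG_act
  trxn <- fe$barriers$dG_rxn
  # targets equal to the current system: returned unchanged within tolerance
  cal0 <- calibrate_reference(base, tact, trxn, tolerance = 0.1)
  expect_true(cal0$converged)
  expect_equal(cal0$alpha, -2, tolerance = 0.1)
  expect_equal(cal0$h12, 0.8, tolerance = 0.1)
  # start far away: barriers recovered within tolerance
  far <- base
  far$topology$state2$alpha <- 0
  far$topology$h12 <- 0.3
  cal <- calibrate_reference(far, tact, trxn, tolerance = 0.1)
  expect_true(cal$converged)
  expect_lt(abs(cal$dG_act - tact), 0.1)
  expect_lt(abs(cal$dG_rxn - trxn), 0.1)
  expect_error(calibrate_reference(base, -1, -3), "infeasible")
})

test_that("replicate s.e.m. does not grow as replicates quadruple (seed majority)", {
  hd <- make_harmonic_diabat_system()
  shrunk <- vapply(1:3, function(sd) {
    sems <- vapply(c(2, 8), function(nr) {
      fe <- evb_free_energy(hd$topology, hd$conformation, n_windows = 7,
                            steps_per_window = 1500, n_replicates = nr,
                            seed = 41 + 100 * sd, frozen_atoms = hd$frozen,
                            n_bins = 30, min_samples = 5)
      fe$barriers$sem_act
    }, 0)
    sems[2] <= sems[1]
  }, TRUE)
  expect_gte(sum(shrunk), 2)
})
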