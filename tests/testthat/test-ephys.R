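test_that("the Boltzmann fit inverts noiseless activation data", {
  v <- seq(-50, 50, 5)
  fit <- boltzmann_fit(v, boltzmann(v, 10, 5))
  expect_equal(fit$v_half, 10, tolerance = 1e-6)
  expect_equal(fit$k, 5, tolerance = 1e-6)
  # midpoint property
  expect_equal(boltzmann(10, 10, 5), 0.5)
  expect_error(boltzmann_fit(v[1:3], boltzmann(v[1:3], 10, 5)),
               "at least 4")
})

test_that("V_half is recovered within 1 mV from noisy activation curves", {
  v <- seq(-50, 50, 5)
  errs <- vapply(1:100, function(i) {
    p <- betactin:::with_local_seed(1000 + i,
                                    boltzmann(v, 10, 5) + rnorm(length(v), 0, 0.02))
    abs(boltzmann_fit(v, p)$v_half - 10)
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("activation_fit normalizes peak currents from simulated sweeps", {
  ss <- simulate_sweeps(n_channels = 2000, gamma_ps = 4, v_half = 5, k = 8,
                        n_sweeps = 12, sigma_instr = 0.5, seed = 5)
  fit <- activation_fit(ss)
  dat <- attr(fit, "data")
  expect_equal(max(abs(dat$i_norm)), 1)
  expect_true(is.finite(fit$v_half) && fit$k != 0)
})

test_that("gating charge integration has correct units and linearity", {
  # rectangular 1 pA x 1 ms pulse -> 1.0 fC
  dt <- 0.01
  n <- 401
  tr <- numeric(n)
  t <- (seq_len(n) - 1) * dt
  tr[t >= 2 & t <= 3] <- 1
  g <- gating_record(tr, dt, baseline_start = 0, baseline_end = 1.5,
                     step_start = 2, step_end = 3)
  expect_equal(qon(g), 1.0, tolerance = 1e-9)

  zero <- gating_record(numeric(n), dt, 0, 1.5, 2, 4)
  expect_equal(qon(zero), 0)

  # planted alpha-function charge within 0.5% at dt = 0.01
  ga <- simulate_gating(q_fc = 300, dt = 0.01)
  expect_equal(qon(ga), 300, tolerance = 0.005)

  # linearity: qon(alpha * g) = alpha * qon(g)
  ga2 <- ga; ga2$trace <- 2.5 * ga$trace
  expect_equal(qon(ga2), 2.5 * qon(ga), tolerance = 1e-9)

  expect_error(gating_record(tr, dt, 0, 3, 2, 3), "precede")
})

test_that("noise points compute per-timepoint means and unbiased variances", {
  mk_set <- function(mats) sweep_set(mats, voltages = seq_len(length(mats)),
                                     dt = 1, step_start = 0, step_end = 9,
                                     v_rev = 70)
  # identical repeated sweeps -> zero variance
  m <- matrix(rep(-5, 20), nrow = 10)
  np <- noise_points(mk_set(list(m)))
  expect_equal(np$var_i, 0)
  expect_equal(np$mean_i, -5)

  # two sweeps at constant +1 / -1 pA -> variance 2
  m2 <- cbind(rep(1, 10), rep(-1, 10))
  np2 <- noise_points(mk_set(list(m2)))
  expect_equal(np2$var_i, 2)
  expect_equal(np2$mean_i, 0)

  expect_error(noise_points(mk_set(list(m[, 1, drop = FALSE]))),
               "at least 2 sweeps")
})

test_that("simulated sweep variance matches the binomial moment within 3 SE", {
  n <- 500; g <- 4; vr <- 70
  ss <- simulate_sweeps(n_channels = n, gamma_ps = g, v_half = 5, k = 8,
                        v_rev = vr, voltages = c(0), n_sweeps = 200,
                        sigma_instr = 0, seed = 9)
  np <- noise_points(ss)
  po <- boltzmann(0, 5, 8)
  i <- g * (0 - vr) / 1000
  expect_equal(np$mean_i, n * i * po, tolerance = 0.02)
  v_theory <- n * i^2 * po * (1 - po)
  # SE of a variance estimate over k independent samples ~ v * sqrt(2/(k-1));
  # window points x sweeps are all independent draws here
  k <- 200 * sum(np$n_sweeps > 0)  # sweeps per point; conservative
  se <- v_theory * sqrt(2 / (k - 1))
  expect_lt(abs(np$var_i - v_theory), 3 * se + 0.05 * v_theory)
})

test_that("noise_fit solves the variance-mean line exactly on analytic points", {
  n <- 1000; g <- 4; vr <- 70
  vs <- seq(-30, 40, 5)
  po <- boltzmann(vs, 5, 8)
  i <- g * (vs - vr) / 1000
  pts <- data.frame(voltage = vs, mean_i = n * i * po,
                    var_i = n * i^2 * po * (1 - po), n_sweeps = 100)
  nf <- noise_fit(pts, vr)
  expect_equal(nf$n_channels, n, tolerance = 1e-9)
  expect_equal(nf$gamma_ps, g, tolerance = 1e-9)
  expect_equal(nf$po_max, po[which.max(abs(pts$mean_i))], tolerance = 1e-9)

  # Po -> 1 limit: y -> 0 as x -> n * gamma
  y_at <- nf$points$y[which.max(po)]
  expect_lt(y_at, g / 1000 * (1 - min(po)) )

  # non-negative slope -> channel count unresolvable
  bad <- pts; bad$var_i <- rev(bad$var_i)
  expect_error(noise_fit(bad, vr), "unresolvable")
  expect_error(noise_fit(pts[1:2, ], vr), "at least 3")
  expect_error(noise_fit(transform(pts, voltage = vr), vr), "Vrev")
})

test_that("doubling the unitary current doubles gamma and preserves n", {
  ss <- simulate_sweeps(n_channels = 800, gamma_ps = 4, n_sweeps = 60,
                        sigma_instr = 0, seed = 12)
  np1 <- noise_points(ss)
  np2 <- np1
  np2$mean_i <- 2 * np1$mean_i      # i -> 2i: mean doubles...
  np2$var_i <- 4 * np1$var_i        # ...and variance quadruples
  f1 <- noise_fit(np1, 70)
  f2 <- noise_fit(np2, 70)
  expect_equal(f2$gamma_ps, 2 * f1$gamma_ps, tolerance = 1e-9)
  expect_equal(f2$n_channels, f1$n_channels, tolerance = 1e-9)
})

test_that("bootstrap t-test behaves at the null, under separation, and is consistent", {
  set.seed(30)
  a <- rnorm(10, 5, 1)
  null <- bootstrap_ttest(a, a, n_boot = 20000, seed = 4)
  expect_gt(null$p_value, 0.5)

  b <- a + 10 * sd(a)
  sep <- bootstrap_ttest(a, b, n_boot = 20000, seed = 4)
  expect_lt(sep$p_value, 0.001)

  # bootstrap mean of a group approximates the sample mean
  expect_lt(abs(null$mean_a - mean(a)),
            3 * sd(a) / sqrt(length(a)) / sqrt(20000) * sqrt(length(a)) + 0.01)

  # degenerate equal groups
  deg <- bootstrap_ttest(rep(2, 5), rep(2, 5), n_boot = 1000, seed = 1)
  expect_equal(deg$p_value, 1)
  expect_error(bootstrap_ttest(1:2, 1:5), "at least 3")

  # determinism under a fixed seed
  r1 <- bootstrap_ttest(a, b, n_boot = 5000, seed = 7)
  r2 <- bootstrap_ttest(a, b, n_boot = 5000, seed = 7)
  expect_identical(r1, r2)
})

test_that("sweep sets round-trip through CSV matrices with a JSON sidecar", {
  ss <- simulate_sweeps(n_channels = 100, gamma_ps = 4, voltages = c(-10, 0),
                        n_sweeps = 3, seed = 44)
  dir <- tempfile()
  write_sweep_set(ss, dir)
  back <- read_sweep_set(dir)
  expect_equal(back$voltages, ss$voltages)
  expect_equal(back$dt, ss$dt)
  expect_equal(back$sweeps[[1]], ss$sweeps[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(noise_points(back), noise_points(ss), tolerance = 1e-10)
})
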