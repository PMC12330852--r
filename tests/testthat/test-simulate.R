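test_that("ground-truth responses follow the three-compartment model", {
  sch <- sim_scheme()
  cfg <- ground_truth_config()
  H <- ground_truth_response(cfg, sch)
  ## b = 0 amplitude exactly 1 (unit fractions, S0 = 1)
  expect_equal(H$H[1, 1], sqrt(4 * pi), tolerance = 1e-10)
  expect_equal(H$H[1, -1], numeric(4), tolerance = 1e-10)

  ## pure free water: isotropic
  Hw <- ground_truth_response(ground_truth_config(
    f_stick = 0, f_zeppelin = 0, f_water = 1), sch)
  expect_lt(max(abs(Hw$H[, -1])), 1e-10)
  expect_equal(Hw$H[2, 1] / sqrt(4 * pi), exp(-3), tolerance = 1e-9)

  ## default mixture at b = 1, alpha = 90 deg: direct compartment sum
  prof <- sapply(seq(0, 8, 2), function(l)
    sqrt((2 * l + 1) / (4 * pi)) * legendre_eval(l, 0))
  amp90 <- sum(H$H[2, ] * prof)
  oracle <- 0.45 * 1 + 0.45 * exp(-0.7) + 0.10 * exp(-3)
  expect_equal(amp90, oracle, tolerance = 2e-4)

  ## invalid configurations are rejected
  expect_error(ground_truth_config(f_stick = 0.9), "sum to 1")
  expect_error(ground_truth_config(De_perp = 2.5), "De_perp")

  ## the alternative composition carries its stated values
  alt <- ground_truth_config_alternative()
  expect_equal(c(alt$f_stick, alt$f_zeppelin, alt$f_water),
               c(0.3, 0.4, 0.3))
  expect_equal(alt$De_perp, 1.4)
})

test_that("ground-truth ODFs have the requested fibre geometry", {
  p0 <- ground_truth_odf(0)
  expect_equal(as.numeric(p0)[1], 1 / sqrt(4 * pi), tolerance = 1e-12)
  expect_equal(as.numeric(p0), as.numeric(apodised_delta(c(0, 0, 1))),
               tolerance = 1e-12)

  ## 90 degrees: symmetric under swapping the two fibre axes (x <-> z)
  p90 <- ground_truth_odf(90)
  th <- seq(0, 90, by = 1) * pi / 180
  d1 <- cbind(sin(th), 0, cos(th))
  a <- odf_amplitudes(p90, d1)
  expect_equal(a, rev(a), tolerance = 1e-9)

  ## 60 degrees: two in-plane maxima 60 +/- 2 degrees apart
  p60 <- ground_truth_odf(60)
  th <- seq(-60, 120, by = 0.25) * pi / 180
  a <- odf_amplitudes(p60, cbind(sin(th), 0, cos(th)))
  pk <- which(diff(sign(diff(a))) == -2) + 1
  ## the apodised delta has small side lobes; compare the two dominant
  ## in-plane maxima
  pk <- pk[order(a[pk], decreasing = TRUE)][1:2]
  expect_identical(length(pk), 2L)
  sep <- abs(diff(th[sort(pk)])) * 180 / pi
  expect_lt(abs(sep - 60), 2)
})

test_that("simulated signals obey the physical orderings", {
  sch <- sim_scheme()
  H <- default_response()
  p <- ground_truth_odf(0)
  sig <- simulate_signal(H, p, sch)
  ## b = 0 volumes equal S0 = 1
  expect_equal(sig[sch$shell_index == 1], rep(1, 5), tolerance = 1e-9)
  ## diffusion is fastest along the fibre, so the signal is most
  ## attenuated there: perpendicular amplitude exceeds along-fibre
  ## amplitude for b > 0
  for (s in 2:3) {
    d <- sch$shell_dirs[[s]]
    along <- which.max(abs(d[, 3]))
    perp <- which.min(abs(d[, 3]))
    amp <- sig[sch$shell_index == s]
    expect_gt(amp[perp], amp[along])
  }
})

test_that("Rician noise has the declared law and determinism", {
  expect_identical(add_rician_noise(1:5, Inf), 1:5)
  expect_error(add_rician_noise(1, 0), "snr")

  ## Rayleigh mean at zero signal: sigma * sqrt(pi / 2)
  x <- add_rician_noise(numeric(1e6), snr = 1, seed = 42)
  expect_lt(abs(mean(x) - sqrt(pi / 2)),
            3 * sqrt((2 - pi / 2)) / sqrt(1e6))

  ## high-SNR bias: E|S + n| - S ~ sigma^2 / (2 S)
  S <- 1; snr <- 50; sigma <- 1 / snr
  y <- add_rician_noise(rep(S, 1e5), snr, seed = 43)
  expect_lt(abs(mean(y) - S - sigma^2 / (2 * S)),
            4 * sigma / sqrt(1e5))

  ## channel variance matches sigma^2 (via the second moment:
  ## E[R^2] = S^2 + 2 sigma^2)
  expect_lt(abs(mean(y^2) - (S^2 + 2 * sigma^2)), 5 * sigma / sqrt(1e5))

  ## determinism per seed
  expect_identical(add_rician_noise(1:10 / 10, 20, seed = 7),
                   add_rician_noise(1:10 / 10, 20, seed = 7))
})

test_that("the repeated-fit experiment produces a deterministic tidy table", {
  cfg <- ground_truth_config(crossing_angle = 0)
  res <- run_acc_experiment(list(default = cfg), scheme = sim_scheme(),
                            snrs = c(Inf, 50), n_reps = 2L, seed = 123L)
  expect_s3_class(res, "data.frame")
  expect_identical(nrow(res), 8L)   # 2 snr x 2 reps x 2 methods
  expect_setequal(unique(res$method), c("loresd", "msmt_csd"))
  expect_true(all(res$converged))

  ## noiseless: both methods essentially exact
  noiseless <- subset(res, !is.finite(snr))
  expect_true(all(noiseless$acc > 0.99))

  ## determinism: identical rerun
  res2 <- run_acc_experiment(list(default = cfg), scheme = sim_scheme(),
                             snrs = c(Inf, 50), n_reps = 2L, seed = 123L)
  expect_identical(res, res2)

  ## summary carries mean and quartiles per condition
  sm <- summary(res)
  expect_true(all(c("mean", "q1", "median", "q3") %in% names(sm)))
  expect_identical(nrow(sm), 4L)
})
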