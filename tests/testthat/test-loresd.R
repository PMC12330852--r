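test_that("the objective vanishes on exact forward data and the gradient is analytic", {
  sch <- sim_scheme()
  dict <- default_dict()
  ## exact forward model: zero data term
  pt <- random_feasible(1)
  H <- assemble_response(pt$f, dict, 1)
  sig <- simulate_signal(H, pt$p, sch)
  ssh <- shell_signal(sig, sch)
  expect_lt(loresd_objective(pt$f, pt$p, ssh, dict, reg_lambda = 0), 1e-12)

  ## gradient of the data term is zero at the global minimum
  g <- loresd_gradient(pt$f, pt$p, ssh, dict, reg_lambda = 0)
  expect_lt(max(abs(g)), 1e-10)

  ## isotropic mixture: the regularisation term is exactly zero
  iso_nodes <- dict$grid$nodes[, 1] == dict$grid$nodes[, 2]
  f_iso <- as.numeric(iso_nodes) / sum(iso_nodes)
  expect_equal(
    loresd_objective(f_iso, pt$p, ssh, dict, reg_lambda = 1),
    loresd_objective(f_iso, pt$p, ssh, dict, reg_lambda = 0),
    tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences", {
  sch <- sim_scheme()
  dict <- default_dict()
  H <- default_response()
  sig <- add_rician_noise(simulate_signal(H, ground_truth_odf(60), sch),
                          30, seed = 99)
  ssh <- shell_signal(sig, sch)
  p00 <- 1 / sqrt(4 * pi)
  for (seed in 1:3) {
    pt <- random_feasible(seed)
    x <- c(pt$f, as.numeric(pt$p)[-1])
    fn <- function(x) loresd_objective(x[1:55], c(p00, x[56:99]), ssh, dict,
                                       reg_lambda = 1e-3)
    ga <- loresd_gradient(pt$f, pt$p, ssh, dict, reg_lambda = 1e-3)
    gn <- fd_gradient(fn, x)
    expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-5)
  }
})

test_that("initialisation is the uniform mixture plus one CSD iteration", {
  sch <- sim_scheme()
  dict <- default_dict()
  H <- default_response()
  p <- ground_truth_odf(0)
  sig <- simulate_signal(H, p, sch)
  init <- loresd_init(shell_signal(sig, sch), dict)
  expect_identical(init$f, rep(1 / 55, 55))
  expect_false(init$degenerate)
  ## the single CSD iteration already points at the fibre
  expect_gt(acc(init$p, p), 0.8)
  ## the initial ODF is feasible
  Q <- constraint_directions(300L)
  expect_gt(min(odf_amplitudes(init$p, Q)), -1e-6)

  ## degenerate all-zero signal: isotropic ODF, flagged
  init0 <- loresd_init(shell_signal(numeric(261), sch), dict)
  expect_true(init0$degenerate)
  expect_identical(as.numeric(init0$p)[-1], numeric(44))
})

test_that("fitted voxels satisfy the constraints and report diagnostics", {
  sch <- sim_scheme()
  dict <- default_dict()
  sig <- add_rician_noise(
    simulate_signal(default_response(), ground_truth_odf(60), sch),
    20, seed = 5)
  fit <- loresd(sig, sch, loresd_config(), dict)
  f <- as.numeric(coef(fit)$f)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(sum(f), 1, tolerance = 1e-6)
  Q <- constraint_directions(300L)
  expect_gt(min(odf_amplitudes(fit$p, Q)), -1e-6)
  expect_true(fit$converged)
  expect_gte(fit$rmse, 0)
  expect_identical(fit$k_params, 98L)
  expect_equal(fit$aic,
               aic_gaussian(sum(residuals(fit)^2), 261L, 98L),
               tolerance = 1e-12)
  ## deterministic: same inputs, same result
  fit2 <- loresd(sig, sch, loresd_config(), dict)
  expect_identical(as.numeric(fit$p), as.numeric(fit2$p))
  expect_identical(as.numeric(fit$f), as.numeric(fit2$f))
})

test_that("the fit is equivariant under signal rescaling", {
  sch <- sim_scheme()
  dict <- default_dict()
  sig <- add_rician_noise(
    simulate_signal(default_response(), ground_truth_odf(0), sch),
    50, seed = 17)
  f1 <- loresd(sig, sch, loresd_config(), dict)
  f10 <- loresd(10 * sig, sch, loresd_config(), dict)
  ## internal S0 normalisation makes equivariance exact up to the
  ## round-off of the x10 input itself
  expect_lt(max(abs(as.numeric(f10$p) - as.numeric(f1$p))), 1e-6)
  expect_lt(max(abs(f10$H$H - 10 * f1$H$H)), 1e-6)
  expect_equal(f10$S0, 10 * f1$S0, tolerance = 1e-9)
})

test_that("noiseless on-model recovery is accurate and lambda = 0 is exact", {
  sch <- sim_scheme()
  dict <- default_dict()
  ## on-model: ground-truth response assembled from grid nodes
  gx <- dict$grid$axis
  key <- paste(dict$grid$nodes[, 1], dict$grid$nodes[, 2])
  f3 <- numeric(55)
  f3[match(paste(gx[6], gx[1]), key)] <- 0.45
  f3[match(paste(gx[5], gx[2]), key)] <- 0.45
  f3[match(paste(gx[8], gx[8]), key)] <- 0.10
  H <- assemble_response(f3, dict, 1)
  p <- ground_truth_odf(0)
  sig <- simulate_signal(H, p, sch)
  cfg0 <- loresd_config(reg_lambda = 0, rel_ftol = 1e-10, max_iter = 2000L)
  fit0 <- loresd(sig, sch, cfg0, dict)
  expect_gt(acc(fit0$p, p), 0.999)
  expect_lt(fit0$rmse, 1e-4)

  ## contrast recovery within 0.1 of the ground-truth fractions at the
  ## default regularisation
  fit <- loresd(sig, sch, loresd_config(rel_ftol = 1e-6, max_iter = 1000L),
                dict)
  g <- dict$grid
  for (nm in c("intra", "extra", "free_water")) {
    truth <- contrast_value(contrast_matrix(nm, g), f3)
    expect_lt(abs(contrast_value(contrast_matrix(nm, g), fit$f) - truth),
              0.1)
  }
})

test_that("anisotropic response energy is monotone in the regularisation", {
  sch <- sim_scheme()
  dict <- default_dict()
  sig <- simulate_signal(default_response(), ground_truth_odf(0), sch)
  en <- sapply(c(0, 1e-3, 1e-1), function(lam) {
    fit <- loresd(sig, sch,
                  loresd_config(reg_lambda = lam, rel_ftol = 1e-6,
                                max_iter = 1000L), dict)
    sum(fit$H$H[, -1]^2)
  })
  expect_true(all(diff(en) <= 1e-8))
})

test_that("parameter counting and AIC follow their closed forms", {
  expect_identical(parameter_count("lore_sd", lmax = 8L), 98L)
  expect_identical(parameter_count("msmt_csd", lmax = 8L, n_iso = 2L), 47L)
  expect_identical(
    parameter_count("lore_sd", lmax = 0L,
                    grid = diffusivity_grid(1L, c(0, 0))), 0L)
  expect_error(parameter_count("dti"), "arg")

  expect_equal(aic_gaussian(10, 10, 0), 0, tolerance = 1e-12)
  expect_equal(aic_gaussian(5, 50, 8) - aic_gaussian(5, 50, 4), 8,
               tolerance = 1e-12)
  expect_warning(a <- aic_gaussian(0, 10, 3), "-Inf")
  expect_identical(a, -Inf)
  ## nested comparison: the lower-rss model wins iff the improvement
  ## beats the 2 * delta-k penalty
  rss1 <- 100; n <- 261
  for (rss2 in c(95, 60)) {
    d <- aic_gaussian(rss2, n, 98) - aic_gaussian(rss1, n, 47)
    wins <- n * log(rss2 / rss1) < -2 * (98 - 47)
    expect_identical(d < 0, wins)
  }

  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_identical(rmse(1:5, 1:5), 0)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})
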