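test_that("SH basis is orthonormal and has the declared shape", {
  expect_identical(sh_ncoef(8L), 45L)
  expect_identical(sh_ncoef(0L), 1L)
  expect_error(sh_basis_matrix(diag(3), 7), "even")
  expect_error(sh_basis_matrix(2 * diag(3), 8L), "unit")

  ## Y00 is the constant 1/sqrt(4*pi)
  Y <- sh_basis_matrix(matrix(c(0, 0, 1), 1), 0L)
  expect_equal(Y[1, 1], 1 / sqrt(4 * pi), tolerance = 1e-12)

  ## Monte-Carlo Gram matrix ~ identity (orthonormality)
  dirs <- uniform_directions(5000L, seed = 5L, iterations = 0L)
  Y <- sh_basis_matrix(dirs, 4L)
  G <- crossprod(Y) * 4 * pi / nrow(dirs)
  expect_lt(max(abs(G - diag(ncol(Y)))), 1e-2)
})

test_that("per-shell SH fitting round-trips band-limited signals", {
  dirs <- uniform_directions(128L, seed = 2L)
  ## constant amplitude at lmax 0 -> c * sqrt(4*pi)
  cf <- fit_shell_sh(rep(2.5, 60), uniform_directions(60L, seed = 3L), 0L)
  expect_equal(cf[1], 2.5 * sqrt(4 * pi), tolerance = 1e-10)

  ## band-limited round trip at lmax 4
  set.seed(42)
  truth <- rnorm(sh_ncoef(4L))
  amp <- drop(sh_basis_matrix(dirs, 4L) %*% truth)
  expect_equal(fit_shell_sh(amp, dirs, 4L), truth, tolerance = 1e-10)

  ## super-band-limited input: residual equals the energy of the dropped
  ## orders as projected on these directions (direct projection oracle)
  set.seed(43)
  c12 <- rnorm(sh_ncoef(12L))
  Y12 <- sh_basis_matrix(dirs, 12L)
  amp12 <- drop(Y12 %*% c12)
  cf8 <- fit_shell_sh(amp12, dirs, 8L)
  res <- amp12 - drop(sh_basis_matrix(dirs, 8L) %*% cf8)
  ## oracle: residual of the explicit least-squares projection
  Y8 <- Y12[, seq_len(sh_ncoef(8L))]
  res_oracle <- amp12 - Y8 %*% qr.coef(qr(Y8), amp12)
  expect_equal(sum(res^2), sum(res_oracle^2), tolerance = 1e-10)
  expect_gt(sum(res^2), 0)

  expect_error(fit_shell_sh(rep(1, 10), uniform_directions(10L), 8L),
               "lower lmax")
})

test_that("zonal projection matches quadrature oracles", {
  ## constant kernel: only l = 0, value sqrt(4*pi)
  h <- zonal_projection(function(t) rep(1, length(t)), 4L)
  expect_equal(h[1], sqrt(4 * pi), tolerance = 1e-12)
  expect_equal(h[-1], numeric(2), tolerance = 1e-12)

  ## cos^2: only l = 0 and l = 2 (P2 expansion)
  h <- zonal_projection(function(t) t^2, 8L)
  expect_true(all(abs(h[3:5]) < 1e-12))
  expect_gt(abs(h[2]), 0.1)

  ## Gaussian kernel vs an independent Gauss-Legendre oracle at a
  ## different node count
  kern <- function(t) exp(-0.7) * exp(-(2.2 - 0.7) * t^2)
  h <- zonal_projection(kern, 8L)
  gl <- pracma::gaussLegendre(96, -1, 1)
  legp <- function(l, x) {
    p0 <- rep(1, length(x)); if (l == 0) return(p0)
    p1 <- x
    if (l > 1) for (k in 2:l) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k; p0 <- p1; p1 <- p2
    }
    p1
  }
  oracle <- sapply(seq(0, 8, 2), function(l)
    2 * pi * sqrt((2 * l + 1) / (4 * pi)) *
      sum(gl$w * kern(gl$x) * legp(l, gl$x)))
  expect_equal(h, oracle, tolerance = 1e-8)

  expect_error(zonal_projection(function(t) t, 8L,
                                quad = gauss_legendre(4L)), "quadrature")
})

test_that("spherical convolution is the per-degree scaled outer product", {
  sch <- sim_scheme()
  ## isotropic response: direction-independent signal per shell
  iso <- response_function(gaussian_kernel_zh(1.5, 1.5, sch, 8L),
                           sch$shell_b)
  p <- apodised_delta(c(1, 1, 1), 8L)
  sig <- simulate_signal(iso, p, sch)
  for (s in seq_along(sch$shell_b)) {
    amp <- sig[sch$shell_index == s]
    expect_lt(diff(range(amp)), 1e-9)
  }

  ## lmax mismatch is an error
  expect_error(spherical_convolve(iso, odf(numeric(15), 4L)), "lmax")

  ## bilinearity
  H1 <- gaussian_kernel_zh(2.2, 0, sch, 8L)
  H2 <- gaussian_kernel_zh(1.0, 0.5, sch, 8L)
  r1 <- response_function(H1, sch$shell_b)
  r2 <- response_function(H2, sch$shell_b)
  r12 <- response_function(2 * H1 + 3 * H2, sch$shell_b)
  s1 <- simulate_signal(r1, p, sch)
  s2 <- simulate_signal(r2, p, sch)
  s12 <- simulate_signal(r12, p, sch)
  expect_equal(s12, 2 * s1 + 3 * s2, tolerance = 1e-12)

  ## convolving a zonal Gaussian with a (truncated) delta along z
  ## reproduces the kernel profile at the sample directions, within the
  ## band-limit error of the truncation
  pz <- sh_basis_matrix(matrix(c(0, 0, 1), 1), 8L)[1, ]
  sig <- shell_signal_amplitudes(
    spherical_convolve(response_function(H1, sch$shell_b), odf(pz, 8L)),
    sch)
  direct <- exp(-sch$shell_b[sch$shell_index] * 2.2 * sch$bvecs[, 3]^2)
  ## truncated delta: band-limit error only (the kernel is smooth)
  expect_lt(max(abs(sig - direct)), 1e-2)
})

test_that("uniform directions are unit-norm, deterministic and well spread", {
  d1 <- uniform_directions(300L, seed = 300L)
  expect_identical(dim(d1), c(300L, 3L))
  expect_equal(max(abs(sqrt(rowSums(d1^2)) - 1)), 0, tolerance = 1e-12)
  d2 <- uniform_directions(300L, seed = 300L)
  expect_identical(d1, d2)
  expect_identical(dim(uniform_directions(1L)), c(1L, 3L))

  ## packing quality: minimum antipodal angle within 20% of the hexagonal
  ## packing estimate for n antipodal pairs (repulsion optimum proxy)
  d <- uniform_directions(128L, seed = 1L)
  hex <- sqrt(8 * pi / (sqrt(3) * 2 * 128)) * 180 / pi
  expect_gt(attr(d, "min_angle"), 0.8 * hex)
})

test_that("the shipped constraint directions match the generator", {
  d <- constraint_directions(300L)
  expect_identical(dim(d), c(300L, 3L))
  gen <- uniform_directions(300L, seed = 300L)
  expect_equal(d, unclass(gen)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("apodised deltas are sharp, nonnegative and unit-normalised", {
  del <- apodised_delta(c(0, 0, 1), 8L)
  expect_equal(as.numeric(del)[1], 1 / sqrt(4 * pi), tolerance = 1e-12)

  ## peak at the pole over the 300-direction grid plus the pole itself
  grid <- rbind(constraint_directions(300L), c(0, 0, 1))
  amp <- odf_amplitudes(del, grid)
  expect_identical(which.max(amp), nrow(grid))

  ## nonnegative on a dense scan
  dense <- uniform_directions(10000L, seed = 9L, iterations = 0L)
  expect_gt(min(odf_amplitudes(del, dense)), -1e-6)

  ## unit integral (Monte-Carlo spherical quadrature)
  expect_equal(mean(odf_amplitudes(del, dense)) * 4 * pi, 1,
               tolerance = 1e-2)
  ## ... and exactly via the l = 0 coefficient
  expect_equal(as.numeric(del)[1] * sqrt(4 * pi), 1, tolerance = 1e-12)

  ## rotation equivariance: coefficients of a rotated delta equal the
  ## refitted amplitudes of the original evaluated on rotated directions
  ax <- c(1, 2, 0.5); ax <- ax / sqrt(sum(ax^2))
  del2 <- apodised_delta(ax, 8L)
  dirs <- uniform_directions(200L, seed = 4L)
  ## build rotation taking z to ax
  v <- c(0, 0, 1)
  rot <- rotation_between(v, ax)
  refit <- fit_shell_sh(odf_amplitudes(del, dirs %*% rot), dirs, 8L)
  expect_equal(refit, as.numeric(del2), tolerance = 1e-8)

  expect_error(apodised_delta(c(0, 0, 0), 8L), "non-zero")
})

test_that("the angular correlation coefficient behaves per its definition", {
  u <- apodised_delta(c(0, 0, 1), 8L)
  expect_equal(acc(u, u), 1, tolerance = 1e-12)
  expect_equal(acc(u, odf(-as.numeric(u), 8L)), -1, tolerance = 1e-12)

  ## invariance to isotropic rescaling and to the l = 0 coefficient
  v <- as.numeric(u) * 3.7
  v[1] <- 99
  expect_equal(acc(u, odf(v, 8L)), 1, tolerance = 1e-12)

  ## deltas at 0 and 90 degrees: oracle by explicit rotation (refit of
  ## rotated amplitude samples) and direct evaluation of the definition
  w <- apodised_delta(c(1, 0, 0), 8L)
  dirs <- uniform_directions(200L, seed = 6L)
  rot <- rotation_between(c(0, 0, 1), c(1, 0, 0))
  wr <- fit_shell_sh(odf_amplitudes(u, dirs %*% rot), dirs, 8L)
  uu <- as.numeric(u)[-1]; vv <- wr[-1]
  oracle <- sum(uu * vv) / sqrt(sum(uu^2) * sum(vv^2))
  expect_equal(acc(u, w), oracle, tolerance = 1e-6)

  ## undefined for isotropic input
  iso <- odf(c(1 / sqrt(4 * pi), numeric(44)), 8L)
  expect_error(acc(iso, u), "undefined")
})

test_that("acc is invariant under simultaneous rotation of both arguments", {
  u <- apodised_delta(c(0, 0, 1), 8L)
  v <- odf(0.6 * as.numeric(apodised_delta(c(0.3, 0, 1), 8L)) +
           0.4 * as.numeric(apodised_delta(c(1, 0.2, 0.1), 8L)), 8L)
  ref <- acc(u, v)
  dirs <- uniform_directions(200L, seed = 8L)
  for (seed in 1:3) {
    set.seed(seed)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    rot <- rotation_between(c(0, 0, 1), ax)
    ur <- fit_shell_sh(odf_amplitudes(u, dirs %*% rot), dirs, 8L)
    vr <- fit_shell_sh(odf_amplitudes(v, dirs %*% rot), dirs, 8L)
    expect_equal(acc(odf(ur, 8L), odf(vr, 8L)), ref, tolerance = 1e-6)
  }
})
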