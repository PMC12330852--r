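# Shared fixtures, built in code and memoised for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## default simulation scheme: b = 0/1/2 ms/um^2 with 5/128/128 directions
sim_scheme <- function() memo("scheme", simulation_scheme())

default_dict <- function() memo("dict",
  build_dictionary(diffusivity_grid(), sim_scheme(), 8L))

default_response <- function() memo("H_default",
  ground_truth_response(ground_truth_config(), sim_scheme(), 8L))

iso_set <- function() memo("iso", {
  sch <- sim_scheme()
  list(gm = response_function(gaussian_kernel_zh(0.8, 0.8, sch, 0L),
                              sch$shell_b),
       csf = response_function(gaussian_kernel_zh(3, 3, sch, 0L),
                               sch$shell_b))
})

default_tissue_responses <- function() memo("tissue",
  tissue_responses(default_response(), iso_set()))

## light-weight setting for I/O and CLI tests
small_scheme <- function() memo("small_scheme",
  simulation_scheme(ndirs = c(3L, 24L, 24L), seed = 11L))

small_config <- function() memo("small_config",
  loresd_config(lmax = 4L, grid = diffusivity_grid(5L)))

small_dict <- function() memo("small_dict",
  build_dictionary(diffusivity_grid(5L), small_scheme(), 4L))

## central finite differences of a scalar function
fd_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

## random feasible (f, p) point: Dirichlet-ish fractions, ODF from a noisy
## nonnegative mixture of deltas (guaranteed feasible by construction)
random_feasible <- function(seed, lmax = 8L, n_nodes = 55L) {
  set.seed(seed)
  f <- stats::rexp(n_nodes)
  f <- f / sum(f)
  w1 <- stats::runif(1)
  d1 <- apodised_delta(stats::rnorm(3), lmax)
  d2 <- apodised_delta(stats::rnorm(3), lmax)
  p <- w1 * as.numeric(d1) + (1 - w1) * as.numeric(d2)
  list(f = f, p = odf(p, lmax, normalised = TRUE))
}

## rotation matrix taking unit vector a to unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))  # antipodal: flip
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

## Legendre polynomial P_l(x) (independent small oracle for tests)
legendre_eval <- function(l, x) {
  p0 <- rep(1, length(x)); if (l == 0) return(p0)
  p1 <- x
  if (l > 1) for (k in 2:l) {
    p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    p0 <- p1; p1 <- p2
  }
  p1
}
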