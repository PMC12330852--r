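#' Real symmetric spherical harmonics
#'
#' The package uses the real, symmetric (even-order-only) spherical harmonic
#' basis in the MRtrix3 convention: orthonormal over the sphere, coefficients
#' ordered by degree `l = 0, 2, ..., lmax` and, within each degree, by
#' `m = -l, ..., l` (sine terms for negative `m`, cosine terms for positive
#' `m`). Antipodally symmetric spherical functions -- ODFs and axially
#' symmetric response kernels -- are fully described in this basis.
#'
#' @name sh-basis
#' @keywords internal
NULL

#' Number of even-order SH coefficients
#'
#' @param lmax Maximum (even) spherical harmonic degree.
#' @return Integer: `(lmax + 1) * (lmax + 2) / 2`, e.g. 45 at `lmax = 8`.
#' @export
sh_ncoef <- function(lmax) {
  check_lmax(lmax)
  as.integer((lmax + 1L) * (lmax + 2L) / 2L)
}

#' Even degrees up to lmax
#' @param lmax Maximum even degree.
#' @return Integer vector `c(0, 2, ..., lmax)`.
#' @export
sh_degrees <- function(lmax) {
  check_lmax(lmax)
  seq.int(0L, lmax, by = 2L)
}

## degree of each coefficient column, in the declared ordering
sh_coef_degree <- function(lmax) {
  ls <- sh_degrees(lmax)
  rep.int(ls, 2L * ls + 1L)
}

## per-degree zonal convolution normalisation N_l = sqrt(4*pi / (2l + 1))
sh_nl <- function(lmax) {
  ls <- sh_degrees(lmax)
  sqrt(4 * pi / (2 * ls + 1))
}

check_lmax <- function(lmax) {
  if (length(lmax) != 1L || is.na(lmax) || lmax < 0 || lmax %% 2 != 0)
    stop("'lmax' must be a single even integer >= 0", call. = FALSE)
  invisible(lmax)
}

check_unit_dirs <- function(directions, tol = 1e-10) {
  if (is.vector(directions)) directions <- matrix(directions, nrow = 1L)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("directions must be an n x 3 matrix of unit vectors", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > sqrt(tol)))
    stop("all directions must have unit Euclidean norm", call. = FALSE)
  directions
}

## Legendre polynomial P_l(x), upward recursion
legendre_p <- function(l, x) {
  p0 <- rep.int(1, length(x))
  if (l == 0L) return(p0)
  p1 <- x
  if (l > 1L) {
    for (k in 2:l) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1
      p1 <- p2
    }
  }
  p1
}

## associated Legendre P_l^m(x) for all 0 <= m <= l <= lmax (no
## Condon-Shortley phase); returns a named list indexed "l m"
assoc_legendre_all <- function(x, lmax) {
  out <- vector("list", (lmax + 1L)^2)
  key <- function(l, m) l * (lmax + 1L) + m + 1L
  somx2 <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:lmax) {
    pmm <- if (m == 0L) rep.int(1, length(x))
           else prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
    out[[key(m, m)]] <- pmm
    if (m < lmax) out[[key(m + 1L, m)]] <- x * (2 * m + 1) * pmm
    if (m + 2L <= lmax) {
      for (l in (m + 2L):lmax) {
        out[[key(l, m)]] <-
          ((2 * l - 1) * x * out[[key(l - 1L, m)]] -
             (l + m - 1) * out[[key(l - 2L, m)]]) / (l - m)
      }
    }
  }
  attr(out, "key") <- key
  out
}

#' Evaluate the real symmetric SH basis on a direction set
#'
#' Returns the matrix `Y` with one row per direction and one column per
#' `(l, m)` pair with even `l <= lmax`, in the declared coefficient ordering.
#' The basis is orthonormal: the Gram matrix of `Y` under uniform spherical
#' quadrature is the identity.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param lmax Maximum even SH degree.
#' @return n x `sh_ncoef(lmax)` numeric matrix of basis amplitudes.
#' @export
sh_basis_matrix <- function(directions, lmax) {
  check_lmax(lmax)
  directions <- check_unit_dirs(directions)
  ct <- pmin(1, pmax(-1, directions[, 3L]))
  phi <- atan2(directions[, 2L], directions[, 1L])
  P <- assoc_legendre_all(ct, lmax)
  key <- attr(P, "key")
  ls <- sh_degrees(lmax)
  Y <- matrix(0, nrow(directions), sh_ncoef(lmax))
  j <- 0L
  for (l in ls) {
    for (m in (-l):l) {
      j <- j + 1L
      am <- abs(m)
      K <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lfactorial(l - am) - lfactorial(l + am)))
      p <- P[[key(l, am)]]
      Y[, j] <- if (m < 0L) sqrt(2) * K * p * sin(am * phi)
                else if (m == 0L) K * p
                else sqrt(2) * K * p * cos(am * phi)
    }
  }
  Y
}

#' Least-squares SH fit of sampled spherical amplitudes
#'
#' Projects per-direction amplitudes onto the even-order SH basis. The fit is
#' exact (to round-off) when the sampled function is band-limited at or below
#' `lmax` and the directions are non-degenerate.
#'
#' @param amplitudes Numeric vector, one value per direction.
#' @param directions n x 3 matrix of unit vectors.
#' @param lmax Maximum even SH degree; needs `n >= sh_ncoef(lmax)`.
#' @return Numeric vector of `sh_ncoef(lmax)` coefficients.
#' @export
fit_shell_sh <- function(amplitudes, directions, lmax) {
  directions <- check_unit_dirs(directions)
  if (length(amplitudes) != nrow(directions))
    stop("length(amplitudes) must match the number of directions", call. = FALSE)
  nc <- sh_ncoef(lmax)
  if (length(amplitudes) < nc)
    stop(sprintf(paste0("underdetermined SH fit: %d samples for %d ",
                        "coefficients; lower lmax"),
                 length(amplitudes), nc), call. = FALSE)
  Y <- sh_basis_matrix(directions, lmax)
  qr.coef(qr(Y), amplitudes)
}

#' Gauss-Legendre quadrature on [-1, 1]
#'
#' Thin wrapper around [pracma::gaussLegendre()] used for zonal-harmonic
#' projections of axially symmetric kernels.
#'
#' @param n Number of nodes.
#' @return List with `nodes` and `weights`.
#' @export
gauss_legendre <- function(n = 64L) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  list(nodes = gl$x, weights = gl$w)
}

#' Zonal-harmonic projection of an axially symmetric kernel
#'
#' Computes the `m = 0` (zonal) SH coefficients of an axially symmetric
#' function of the elevation angle, supplied either as a function of
#' `cos(alpha)` or as samples on a Gauss-Legendre grid covering `[-1, 1]`.
#' The projection is the Legendre expansion
#' `h_l = 2*pi * sqrt((2l+1)/(4*pi)) * integral f(t) P_l(t) dt`, consistent
#' with [sh_basis_matrix()]: evaluating the zonal coefficients through the
#' full basis along the kernel axis reproduces the profile for band-limited
#' kernels.
#'
#' @param kernel Function of `t = cos(alpha)` on `[-1, 1]`, or a numeric
#'   vector of samples at `quad$nodes`.
#' @param lmax Maximum even SH degree.
#' @param quad Quadrature rule from [gauss_legendre()].
#' @return Numeric vector of zonal coefficients, one per even degree.
#' @export
zonal_projection <- function(kernel, lmax, quad = gauss_legendre()) {
  check_lmax(lmax)
  if (length(quad$nodes) < lmax + 1L)
    stop("too few quadrature nodes for the requested lmax", call. = FALSE)
  if (min(quad$nodes) < -1 - 1e-9 || max(quad$nodes) > 1 + 1e-9 ||
      min(quad$nodes) > -0.9 || max(quad$nodes) < 0.9)
    stop("quadrature nodes must cover [-1, 1]", call. = FALSE)
  f <- if (is.function(kernel)) kernel(quad$nodes) else as.numeric(kernel)
  if (length(f) != length(quad$nodes))
    stop("kernel samples must match the quadrature nodes", call. = FALSE)
  vapply(sh_degrees(lmax), function(l) {
    2 * pi * sqrt((2 * l + 1) / (4 * pi)) *
      sum(quad$weights * f * legendre_p(l, quad$nodes))
  }, numeric(1))
}

## reconstruct an axially symmetric profile from zonal coefficients at
## t = cos(alpha)
zonal_profile <- function(h, tvals, lmax = 2L * (length(h) - 1L)) {
  ls <- sh_degrees(lmax)
  out <- numeric(length(tvals))
  for (i in seq_along(ls)) {
    out <- out + h[i] * sqrt((2 * ls[i] + 1) / (4 * pi)) *
      legendre_p(ls[i], tvals)
  }
  out
}

#' Spherical convolution in the SH domain
#'
#' Convolves a per-shell axially symmetric response function with an ODF.
#' For every shell `b` and even degree `l` the signal coefficients are the
#' scaled outer product `S_l[b, ] = N_l * h_{l,b} * p_l`, with
#' `N_l = sqrt(4*pi / (2l + 1))`. The operation is linear in both arguments.
#' Only `(shell, l)` blocks with `l` at or below the shell's supported degree
#' are populated.
#'
#' @param response A [response_function()] (zonal coefficients per shell).
#' @param odf An [odf()] coefficient vector (or plain numeric of matching
#'   length).
#' @return A `shell_signal` object holding the per-shell coefficient rows.
#' @export
spherical_convolve <- function(response, odf) {
  stopifnot(inherits(response, "response_function"))
  p <- as_odf_vector(odf)
  lmax <- response$lmax
  if (length(p) != sh_ncoef(lmax))
    stop("lmax mismatch between response and ODF", call. = FALSE)
  ls <- sh_degrees(lmax)
  Nl <- sh_nl(lmax)
  nshell <- nrow(response$H)
  present <- response$present
  if (is.null(present)) present <- matrix(TRUE, nshell, length(ls))
  Sl <- vector("list", length(ls))
  j <- 0L
  for (i in seq_along(ls)) {
    l <- ls[i]
    idx <- j + seq_len(2L * l + 1L)
    j <- j + 2L * l + 1L
    M <- matrix(0, nshell, 2L * l + 1L)
    sel <- present[, i]
    if (any(sel)) M[sel, ] <- Nl[i] * response$H[sel, i] %o% p[idx]
    Sl[[i]] <- M
  }
  new_shell_signal(Sl = Sl, present = present, S0 = response$scale,
                  lmax = lmax, bvals = response$bvals)
}

#' Deterministic quasi-uniform directions on the sphere
#'
#' Generates `n` unit vectors by electrostatic repulsion descent from a
#' Fibonacci-hemisphere start, with antipodally symmetric interaction
#' (points repel both the other points and their antipodes), as appropriate
#' for even-order SH sampling where `g` and `-g` are equivalent. The
#' per-iteration displacement is capped so near-antipodal pairs cannot
#' overshoot. Deterministic for a given `(n, seed)`; the seed rotates the
#' Fibonacci start around the z axis.
#'
#' @param n Number of directions (>= 1).
#' @param seed Integer; rotates the deterministic start.
#' @param iterations,step Repulsion descent parameters.
#' @return n x 3 matrix of unit vectors with attribute `min_angle`, the
#'   minimum pairwise (antipodally symmetrised) angle in degrees.
#' @export
uniform_directions <- function(n, seed = 1L, iterations = 100L,
                               step = 0.1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  off <- (seed %% 997) * 2 * pi / 997
  z <- i / n                     # upper hemisphere, area-uniform
  r <- sqrt(pmax(0, 1 - z^2))
  X <- cbind(r * cos(ga * i + off), r * sin(ga * i + off), z)
  if (n > 2L) {
    cap <- 2 / sqrt(n)           # max displacement per iteration
    for (it in seq_len(iterations)) {
      Fr <- matrix(0, n, 3L)
      for (k in seq_len(n)) {
        dif <- matrix(X[k, ], n, 3L, byrow = TRUE) - X
        dm <- sqrt(rowSums(dif^2)); dm[k] <- Inf
        sm <- matrix(X[k, ], n, 3L, byrow = TRUE) + X
        sm2 <- sqrt(rowSums(sm^2)); sm2[sm2 < 1e-12] <- Inf
        Fr[k, ] <- colSums(dif / dm^3) + colSums(sm / sm2^3)
      }
      disp <- step / n * Fr      # force scale grows ~n with point count
      dn <- sqrt(rowSums(disp^2))
      over <- dn > cap
      if (any(over)) disp[over, ] <- disp[over, ] * (cap / dn[over])
      X <- X + disp
      X <- X / sqrt(rowSums(X^2))
    }
  }
  if (n > 1L) {
    cg <- abs(tcrossprod(X))
    diag(cg) <- 0
    attr(X, "min_angle") <- acos(min(1, max(cg))) * 180 / pi
  } else {
    attr(X, "min_angle") <- 180
  }
  X
}

## Apodisation taper: per-degree weights, relative to a pure (truncated)
## delta, of the antipodally symmetrised squared Dirichlet (Fejer-type)
## kernel A(t) = (B(t)^2 + B(-t)^2) / 2 with B = sum_{l<=lmax/2} (2l+1) P_l.
## A is an even polynomial of degree exactly lmax, nonnegative everywhere
## by construction, and among simple closed forms it is the least-smoothed
## (sharpest) taper that guarantees no negative ringing.
apodisation_taper <- function(lmax, quad = gauss_legendre()) {
  ls <- sh_degrees(lmax)
  if (lmax == 0L) return(1)
  Bfun <- function(t) {
    out <- numeric(length(t))
    for (l in 0:(lmax / 2L)) out <- out + (2 * l + 1) * legendre_p(l, t)
    out
  }
  A <- function(t) (Bfun(t)^2 + Bfun(-t)^2) / 2
  Z <- 2 * pi * sum(quad$weights * A(quad$nodes))   # spherical integral
  h <- zonal_projection(function(t) A(t) / Z, lmax, quad)
  h / sqrt((2 * ls + 1) / (4 * pi))
}

#' Apodised delta ODF
#'
#' A band-limited, everywhere-nonnegative spherical delta used as a
#' ground-truth single-fibre ODF. The profile about the requested
#' orientation is the antipodally symmetrised square of the degree-`lmax/2`
#' Dirichlet kernel: exactly representable at `lmax`, nonnegative by
#' construction (no ringing), unit-normalised (integrates to 1 over the
#' sphere), rotation-equivariant, and as sharp as a simple nonnegative
#' band-limited construction allows.
#'
#' @param orientation Length-3 non-zero vector (normalised internally).
#' @param lmax Maximum even SH degree.
#' @return An [odf()] object (normalised).
#' @export
apodised_delta <- function(orientation, lmax = 8L) {
  check_lmax(lmax)
  orientation <- as.numeric(orientation)
  nrm <- sqrt(sum(orientation^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("orientation must be a non-zero vector", call. = FALSE)
  orientation <- orientation / nrm
  w <- apodisation_taper(lmax)
  p <- w[match(sh_coef_degree(lmax), sh_degrees(lmax))] *
    sh_basis_matrix(matrix(orientation, 1L), lmax)[1L, ]
  odf(p, lmax = lmax, normalised = TRUE)
}

#' Angular correlation coefficient between two ODFs
#'
#' Normalised inner product of the `l >= 2` SH coefficients: the cosine
#' similarity of the anisotropic coefficient content. Invariant to positive
#' isotropic rescaling of either argument and to either `l = 0` coefficient.
#'
#' @param u,v ODFs (or coefficient vectors) sharing the same `lmax`.
#' @return Scalar in `[-1, 1]`.
#' @export
acc <- function(u, v) {
  pu <- as_odf_vector(u)
  pv <- as_odf_vector(v)
  if (length(pu) != length(pv))
    stop("ODFs must share the same lmax", call. = FALSE)
  uu <- pu[-1L]
  vv <- pv[-1L]
  eu <- sum(uu^2)
  ev <- sum(vv^2)
  if (eu == 0 || ev == 0)
    stop("ACC is undefined: zero l >= 2 energy in an argument", call. = FALSE)
  sum(uu * vv) / sqrt(eu * ev)
}
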