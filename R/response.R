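#' Triangular diffusivity grid
#'
#' The microstructure representation is a mixture of axially symmetric
#' Gaussian kernels parameterised by axial and radial diffusivity
#' `(lambda_par, lambda_perp)`, placed on a triangular grid: each axis is
#' linearly spaced over `range` (inclusive of both endpoints, so 0 is a
#' node) and only physically valid nodes with
#' `lambda_perp <= lambda_par` are kept. With `n_per_axis = 10` this gives
#' the 55 default nodes.
#'
#' @param n_per_axis Grid points per diffusivity axis.
#' @param range Diffusivity range in um^2/ms.
#' @return Object of class `diffusivity_grid`: `nodes` (matrix with columns
#'   `lpar`, `lperp`, ordered by `lpar` then `lperp`), `axis`, `n_per_axis`,
#'   `range`.
#' @export
diffusivity_grid <- function(n_per_axis = 10L, range = c(0, 4)) {
  stopifnot(n_per_axis >= 1L, length(range) == 2L, range[1L] <= range[2L])
  axis <- seq(range[1L], range[2L], length.out = n_per_axis)
  nodes <- do.call(rbind, lapply(seq_len(n_per_axis), function(i)
    cbind(lpar = axis[i], lperp = axis[seq_len(i)])))
  structure(list(nodes = nodes, axis = axis, n_per_axis = n_per_axis,
                 range = range),
            class = "diffusivity_grid")
}

#' @export
print.diffusivity_grid <- function(x, ...) {
  cat(sprintf("Diffusivity grid: %d x %d on [%g, %g] um^2/ms, %d nodes\n",
              x$n_per_axis, x$n_per_axis, x$range[1L], x$range[2L],
              nrow(x$nodes)))
  invisible(x)
}

#' Zonal coefficients of an axially symmetric Gaussian kernel
#'
#' The per-compartment signal kernel
#' `G(b, alpha) = exp(-b*lambda_perp) * exp(-b*(lambda_par - lambda_perp) * cos(alpha)^2)`
#' projected onto the zonal harmonics for every shell of the scheme, with
#' `b` in ms/um^2 so exponents are dimensionless. At `b = 0` the kernel is
#' the constant 1 (only the `l = 0` coefficient, value `sqrt(4*pi)`).
#'
#' @param lpar,lperp Axial and radial diffusivity in um^2/ms
#'   (`0 <= lperp <= lpar`).
#' @param scheme An [acquisition_scheme()].
#' @param lmax Maximum even SH degree.
#' @param quad Quadrature rule from [gauss_legendre()].
#' @return Matrix of zonal coefficients, shells x even degrees.
#' @export
gaussian_kernel_zh <- function(lpar, lperp, scheme, lmax = 8L,
                               quad = gauss_legendre()) {
  if (lperp > lpar + 1e-12 || lperp < 0)
    stop("need 0 <= lambda_perp <= lambda_par", call. = FALSE)
  stopifnot(inherits(scheme, "acquisition_scheme"))
  nls <- length(sh_degrees(lmax))
  matrix(vapply(scheme$shell_b, function(b) {
    zonal_projection(function(t)
      exp(-b * lperp) * exp(-b * (lpar - lperp) * t^2), lmax, quad)
  }, numeric(nls)), ncol = nls, byrow = TRUE)
}

#' Gaussian kernel dictionary on a diffusivity grid
#'
#' One zonal coefficient matrix per grid node, in node order; cached by the
#' caller and reused across voxels.
#'
#' @param grid A [diffusivity_grid()].
#' @param scheme An [acquisition_scheme()].
#' @param lmax Maximum even SH degree.
#' @return Object of class `kernel_dictionary`: array `G` of dimension
#'   `nodes x shells x degrees`, plus `grid`, `bvals`, `lmax`.
#' @export
build_dictionary <- function(grid, scheme, lmax = 8L) {
  stopifnot(inherits(grid, "diffusivity_grid"))
  quad <- gauss_legendre()
  nls <- length(sh_degrees(lmax))
  nshell <- length(scheme$shell_b)
  G <- array(0, c(nrow(grid$nodes), nshell, nls))
  for (j in seq_len(nrow(grid$nodes))) {
    G[j, , ] <- gaussian_kernel_zh(grid$nodes[j, 1L], grid$nodes[j, 2L],
                                   scheme, lmax, quad)
  }
  structure(list(G = G, grid = grid, bvals = scheme$shell_b, lmax = lmax),
            class = "kernel_dictionary")
}

#' Mixture weights on the diffusivity grid
#'
#' @param f Numeric vector of fractions, one per grid node; must lie in
#'   `[0, 1]` and sum to 1 (tolerance 1e-8).
#' @param grid The [diffusivity_grid()] the fractions live on.
#' @return Object of class `mixture_weights`.
#' @export
mixture_weights <- function(f, grid) {
  f <- as.numeric(f)
  stopifnot(inherits(grid, "diffusivity_grid"))
  if (length(f) != nrow(grid$nodes))
    stop("length(f) must equal the number of grid nodes", call. = FALSE)
  if (any(f < -1e-8) || any(f > 1 + 1e-8))
    stop("mixture fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-8)
    stop("mixture fractions must sum to 1", call. = FALSE)
  structure(f, grid = grid, class = "mixture_weights")
}

as_weight_vector <- function(f) as.numeric(unclass(f))

#' Per-shell response function
#'
#' Zonal coefficient matrix `H` (shells x even degrees) of an axially
#' symmetric response kernel, carrying the signal scale `S0`.
#'
#' @param H Matrix of zonal coefficients, shells x even degrees.
#' @param bvals Shell b-values (ms/um^2).
#' @param scale The `S0` amplitude factor folded into `H`.
#' @param present Optional logical matrix marking measurable
#'   `(shell, degree)` blocks.
#' @return Object of class `response_function`.
#' @export
response_function <- function(H, bvals, scale = 1, present = NULL) {
  H <- as.matrix(H)
  if (nrow(H) != length(bvals))
    stop("nrow(H) must match length(bvals)", call. = FALSE)
  lmax <- 2L * (ncol(H) - 1L)
  structure(list(H = H, bvals = as.numeric(bvals), scale = scale,
                 lmax = lmax, present = present),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("Response function: %d shells, lmax %d, scale %.4g\n",
              nrow(x$H), x$lmax, x$scale))
  invisible(x)
}

#' Assemble a response function from mixture weights
#'
#' `H = S0 * sum_j f_j * G_j`: the S0-scaled convex combination of the
#' dictionary kernels. Linear in both `f` and `S0`.
#'
#' @param f A [mixture_weights()] vector (or plain numeric of node length).
#' @param dictionary A [build_dictionary()] result.
#' @param S0 Signal amplitude scale; a negative value (possible in noisy
#'   data) triggers a warning but proceeds.
#' @return A [response_function()].
#' @export
assemble_response <- function(f, dictionary, S0 = 1) {
  stopifnot(inherits(dictionary, "kernel_dictionary"))
  fv <- as_weight_vector(f)
  if (length(fv) != dim(dictionary$G)[1L])
    stop("mixture length does not match the dictionary", call. = FALSE)
  if (S0 < 0) warning("negative S0; proceeding", call. = FALSE)
  H <- S0 * apply(dictionary$G, c(2L, 3L), function(g) sum(g * fv))
  response_function(H, dictionary$bvals, scale = S0)
}

#' Contrast weight matrix on the diffusivity grid
#'
#' Per-node weights whose inner product with the mixture fractions yields a
#' scalar microstructural contrast. Four built-in contrasts:
#' \describe{
#' \item{intra}{`Wi = exp(-d * lambda_perp)` -- emphasises negligible radial
#'   diffusion (intra-axonal space); `d` controls the decay
#'   (default 10 ms/um^2).}
#' \item{free_water}{1 where both diffusivities are at or above
#'   `fw_threshold` (default 2.6 um^2/ms), else 0.}
#' \item{extra}{`We = 1 - Wi - Wfw`, completing the partition of unity.}
#' \item{anisotropy}{The fractional anisotropy of the axially symmetric
#'   tensor with eigenvalues `(lambda_par, lambda_perp, lambda_perp)`;
#'   defined as 0 at the degenerate node (0, 0).}
#' }
#'
#' @param name One of `"intra"`, `"extra"`, `"free_water"`, `"anisotropy"`.
#' @param grid A [diffusivity_grid()].
#' @param d Exponential decay rate for the intra contrast (ms/um^2).
#' @param fw_threshold Free-water diffusivity cut-off (um^2/ms).
#' @param fw_both If `TRUE` (default) the free-water indicator requires both
#'   diffusivities above threshold (on the triangular grid this equals the
#'   radial condition); if `FALSE` only the axial one.
#' @return Object of class `contrast_matrix`: weights `W` (one per node),
#'   `name`, `grid` and the parameters used.
#' @export
contrast_matrix <- function(name = c("intra", "extra", "free_water",
                                     "anisotropy"),
                            grid = diffusivity_grid(), d = 10,
                            fw_threshold = 2.6, fw_both = TRUE) {
  name <- match.arg(name)
  lpar <- grid$nodes[, 1L]
  lperp <- grid$nodes[, 2L]
  wi <- exp(-d * lperp)
  wfw <- if (fw_both) as.numeric(lpar >= fw_threshold & lperp >= fw_threshold)
         else as.numeric(lpar >= fw_threshold)
  W <- switch(name,
    intra = wi,
    free_water = wfw,
    extra = {
      we <- 1 - wi - wfw
      ## clip only materially negative weights (possible with custom d or
      ## threshold); round-off-scale negatives are kept so the
      ## intra/extra/free-water partition of unity stays exact
      if (any(we < -1e-9)) {
        warning("extra-axonal weights clipped to 0 where Wi + Wfw > 1",
                call. = FALSE)
        we <- pmax(we, 0)
      }
      we
    },
    anisotropy = ifelse(lpar + lperp == 0, 0,
                        (lpar - lperp) / sqrt(lpar^2 + 2 * lperp^2)))
  structure(list(W = W, name = name, grid = grid, d = d,
                 fw_threshold = fw_threshold),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat(sprintf("Contrast matrix '%s': %d nodes, range [%.3g, %.3g]\n",
              x$name, length(x$W), min(x$W), max(x$W)))
  invisible(x)
}

#' Scalar contrast value of a voxel
#'
#' The inner product of a contrast matrix with the voxel's mixture
#' fractions. Lies in `[0, 1]` for weights in `[0, 1]`; the
#' intra/extra/free-water triplet sums to exactly 1 for any valid mixture.
#'
#' @param W A [contrast_matrix()].
#' @param f A [mixture_weights()] vector (or plain numeric of node length).
#' @return Scalar contrast value.
#' @export
contrast_value <- function(W, f) {
  stopifnot(inherits(W, "contrast_matrix"))
  fv <- as_weight_vector(f)
  if (length(fv) != length(W$W))
    stop("mixture and contrast matrix live on different grids", call. = FALSE)
  sum(W$W * fv)
}

#' Modulate an ODF by a scalar contrast
#'
#' Multiplies all SH coefficients by a nonnegative scalar (e.g. a contrast
#' value), producing an amplitude-scaled ODF suitable as tractography input
#' with magnitude-based stopping criteria. Clears the normalised flag; the
#' ACC to the input is preserved exactly.
#'
#' @param p An [odf()].
#' @param s Nonnegative scalar.
#' @return The modulated [odf()].
#' @export
modulate_odf <- function(p, s) {
  if (length(s) != 1L || is.na(s) || s < 0)
    stop("modulation factor must be a nonnegative scalar", call. = FALSE)
  lmax <- attr(p, "lmax")
  odf(as_odf_vector(p) * s, lmax = lmax, normalised = FALSE)
}

#' Export a contrast matrix as a plain-text triangular table
#'
#' One row per node: `lambda_par lambda_perp weight`.
#'
#' @param W A [contrast_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contrast_table <- function(W, path) {
  stopifnot(inherits(W, "contrast_matrix"))
  tab <- cbind(W$grid$nodes, weight = W$W)
  utils::write.table(format(tab, digits = 12), path, quote = FALSE,
                     row.names = FALSE, col.names = c("lpar", "lperp",
                                                      "weight"))
  invisible(path)
}

#' Read a contrast matrix from a triangular table
#'
#' @param path File written by [write_contrast_table()] (or any whitespace
#'   table with columns `lpar`, `lperp`, `weight`).
#' @param grid Grid the weights must match node-for-node.
#' @return A [contrast_matrix()] with `name = "custom"`.
#' @export
read_contrast_table <- function(path, grid = diffusivity_grid()) {
  tab <- utils::read.table(path, header = TRUE)
  if (nrow(tab) != nrow(grid$nodes) ||
      max(abs(tab[[1L]] - grid$nodes[, 1L])) > 1e-6 ||
      max(abs(tab[[2L]] - grid$nodes[, 2L])) > 1e-6)
    stop("contrast table does not match the grid nodes", call. = FALSE)
  structure(list(W = tab[[3L]], name = "custom", grid = grid, d = NA,
                 fw_threshold = NA),
            class = "contrast_matrix")
}
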