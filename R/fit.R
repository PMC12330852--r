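## package-level cache (direction sets, constraint bases)
.loresd_cache <- new.env(parent = emptyenv())

#' Fixed ODF-nonnegativity constraint directions
#'
#' The ODF nonnegativity constraint is evaluated on a fixed quasi-uniform
#' direction set so that results are reproducible bit-for-bit. The default
#' 300-direction set ships with the package as a plain-text fixture; other
#' sizes are generated deterministically by [uniform_directions()] and
#' cached for the session.
#'
#' @param n Number of constraint directions.
#' @return n x 3 matrix of unit vectors.
#' @export
constraint_directions <- function(n = 300L) {
  key <- paste0("dirs", n)
  if (!is.null(.loresd_cache[[key]])) return(.loresd_cache[[key]])
  if (n == 300L) {
    path <- system.file("extdata", "directions300.txt", package = "loresd")
    if (nzchar(path)) {
      d <- as.matrix(utils::read.table(path))
      dimnames(d) <- NULL
      .loresd_cache[[key]] <- d
      return(d)
    }
  }
  d <- uniform_directions(n, seed = 300L)
  .loresd_cache[[key]] <- d
  d
}

constraint_basis <- function(n, lmax) {
  key <- paste0("Y", n, "_", lmax)
  if (is.null(.loresd_cache[[key]]))
    .loresd_cache[[key]] <- sh_basis_matrix(constraint_directions(n), lmax)
  .loresd_cache[[key]]
}

#' Fit configuration
#'
#' Collects the tunable parameters of the joint response/ODF estimator.
#' Defaults follow the reference setting: `lmax = 8`, a 10 x 10 triangular
#' diffusivity grid on `[0, 4]` um^2/ms, regularisation weight
#' `reg_lambda = 1e-3` on the anisotropic response energy, ODF
#' nonnegativity enforced on 300 fixed directions, and a relative function
#' tolerance of 1e-4.
#'
#' @param lmax Maximum even SH degree.
#' @param grid A [diffusivity_grid()].
#' @param reg_lambda Nonnegative regularisation weight.
#' @param n_constraint_dirs Number of ODF nonnegativity directions.
#' @param data_weighting How coefficient blocks enter the data term:
#'   `"block_mean"` (default) weights each `(shell, l)` block by
#'   `1/(2l+1)`, so every degree contributes its mean squared coefficient
#'   residual and the balance against the per-degree response penalty is
#'   independent of block size; `"integral"` uses the plain Frobenius norm
#'   (the spherical-integral reading).
#' @param rel_ftol Relative function tolerance of the solver.
#' @param max_iter Maximum solver iterations.
#' @param n_threads Threads for volume-level fitting.
#' @param seed Base seed recorded in run manifests.
#' @return Object of class `loresd_config`.
#' @export
loresd_config <- function(lmax = 8L, grid = diffusivity_grid(),
                          reg_lambda = 1e-3, n_constraint_dirs = 300L,
                          data_weighting = c("block_mean", "integral"),
                          rel_ftol = 1e-4, max_iter = 200L, n_threads = 1L,
                          seed = 1L) {
  check_lmax(lmax)
  stopifnot(reg_lambda >= 0, rel_ftol > 0, max_iter >= 1)
  structure(list(lmax = as.integer(lmax), grid = grid,
                 reg_lambda = reg_lambda,
                 n_constraint_dirs = as.integer(n_constraint_dirs),
                 data_weighting = match.arg(data_weighting),
                 rel_ftol = rel_ftol, max_iter = as.integer(max_iter),
                 n_threads = as.integer(n_threads), seed = as.integer(seed)),
            class = "loresd_config")
}

## Internal: precomputed per-voxel fitting context.
## B[[i]] = S0 * G[, , i]  (nodes x shells) for degree index i.
## wl[i] is the data-term weight of each degree-l coefficient block: the
## misfit of a (shell, l) block enters as wl * ||residual||^2.
fit_context <- function(signal_sh, dictionary, reg_lambda,
                        data_weighting = c("block_mean", "integral")) {
  lmax <- dictionary$lmax
  stopifnot(signal_sh$lmax == lmax)
  ls <- sh_degrees(lmax)
  data_weighting <- match.arg(data_weighting)
  wl <- switch(data_weighting,
               block_mean = 1 / (2 * ls + 1),
               integral = rep.int(1, length(ls)))
  list(Sl = signal_sh$Sl, present = signal_sh$present, S0 = signal_sh$S0,
       B = lapply(seq_along(ls), function(i)
         signal_sh$S0 * dictionary$G[, , i]),
       ls = ls, Nl = sh_nl(lmax), lambda = reg_lambda, wl = wl)
}

#' Joint objective of the response/ODF estimator
#'
#' The weighted squared coefficient-space misfit plus anisotropic response
#' energy:
#' `sum_l w_l || S_l - N_l H_l(f) p_l' ||_F^2 + lambda * sum_{l>0} || H_l ||_2^2`
#' with `H = S0 * sum_j f_j G_j` and `w_l` the per-degree block weight
#' (`1/(2l+1)` under the default block-mean weighting). Only `(shell, l)`
#' blocks measured at that shell enter the data term (the b = 0 shell
#' contributes only `l = 0`).
#'
#' @param f Mixture fractions (length = grid nodes).
#' @param p ODF coefficient vector (normalised: `p[1] = 1/sqrt(4*pi)`).
#' @param signal_sh A [shell_signal()].
#' @param dictionary A [build_dictionary()] result.
#' @param reg_lambda Regularisation weight.
#' @param data_weighting Data-term block weighting (see [loresd_config()]).
#' @return Nonnegative scalar.
#' @export
loresd_objective <- function(f, p, signal_sh, dictionary, reg_lambda = 1e-3,
                             data_weighting = "block_mean") {
  ctx <- fit_context(signal_sh, dictionary, reg_lambda, data_weighting)
  obj_value(as_weight_vector(f), as_odf_vector(p), ctx)
}

obj_value <- function(f, p, ctx) {
  val <- 0
  j <- 0L
  for (i in seq_along(ctx$ls)) {
    l <- ctx$ls[i]
    idx <- j + seq_len(2L * l + 1L)
    j <- j + 2L * l + 1L
    h <- as.numeric(crossprod(ctx$B[[i]], f))
    sel <- ctx$present[, i]
    R <- ctx$Sl[[i]][sel, , drop = FALSE] -
      ctx$Nl[i] * h[sel] %o% p[idx]
    val <- val + ctx$wl[i] * sum(R * R)
    if (l > 0L) val <- val + ctx$lambda * sum(h * h)
  }
  val
}

#' Analytic gradient of the joint objective
#'
#' Exact partial derivatives with respect to all mixture fractions and all
#' `l >= 2` ODF coefficients (the `l = 0` coefficient is pinned by the
#' normalisation constraint and is not a variable).
#'
#' @inheritParams loresd_objective
#' @return Numeric vector: the fraction gradient followed by the `l >= 2`
#'   coefficient gradient.
#' @export
loresd_gradient <- function(f, p, signal_sh, dictionary, reg_lambda = 1e-3,
                            data_weighting = "block_mean") {
  ctx <- fit_context(signal_sh, dictionary, reg_lambda, data_weighting)
  obj_gradient(as_weight_vector(f), as_odf_vector(p), ctx)
}

obj_gradient <- function(f, p, ctx) {
  nf <- nrow(ctx$B[[1L]])
  gf <- numeric(nf)
  gq <- numeric(length(p) - 1L)
  j <- 0L
  for (i in seq_along(ctx$ls)) {
    l <- ctx$ls[i]
    idx <- j + seq_len(2L * l + 1L)
    j <- j + 2L * l + 1L
    h <- as.numeric(crossprod(ctx$B[[i]], f))
    sel <- ctx$present[, i]
    R <- ctx$Sl[[i]][sel, , drop = FALSE] -
      ctx$Nl[i] * h[sel] %o% p[idx]
    dh <- numeric(length(h))
    dh[sel] <- -2 * ctx$wl[i] * ctx$Nl[i] * as.numeric(R %*% p[idx])
    if (l > 0L) dh <- dh + 2 * ctx$lambda * h
    gf <- gf + as.numeric(ctx$B[[i]] %*% dh)
    if (l > 0L)
      gq[idx - 1L] <- -2 * ctx$wl[i] * ctx$Nl[i] *
        as.numeric(crossprod(R, h[sel]))
  }
  c(gf, gq)
}

## Constrained least-squares ODF for a fixed response (one CSD iteration):
## minimises the data term over p_{l>=2} subject to nonnegative amplitudes
## on the fixed constraint directions, p00 pinned. Convex QP with diagonal
## curvature (per-degree outer-product structure).
csd_step <- function(f, ctx, Q) {
  ncq <- ncol(Q) - 1L
  dl <- numeric(ncq)
  dvec <- numeric(ncq)
  j <- 0L
  for (i in seq_along(ctx$ls)) {
    l <- ctx$ls[i]
    idx <- j + seq_len(2L * l + 1L)
    j <- j + 2L * l + 1L
    if (l == 0L) next
    h <- as.numeric(crossprod(ctx$B[[i]], f))
    sel <- ctx$present[, i]
    dl[idx - 1L] <- 2 * ctx$wl[i] * ctx$Nl[i]^2 * sum(h[sel]^2)
    dvec[idx - 1L] <- 2 * ctx$wl[i] * ctx$Nl[i] *
      as.numeric(crossprod(ctx$Sl[[i]][sel, , drop = FALSE], h[sel]))
  }
  p00 <- 1 / sqrt(4 * pi)
  ridge <- 1e-8 * max(dl, 1)
  sol <- quadprog::solve.QP(Dmat = diag(dl + ridge, ncq), dvec = dvec,
                            Amat = t(Q[, -1L, drop = FALSE]),
                            bvec = -p00 * Q[, 1L])
  c(p00, sol$solution)
}

#' Initialisation of the joint fit
#'
#' Uniform mixture fractions (`1/n_nodes` each) followed by a single CSD
#' iteration: the constrained least-squares ODF for the uniform-mixture
#' response, with nonnegativity on the fixed constraint directions and the
#' `l = 0` coefficient pinned at `1/sqrt(4*pi)`. Deterministic. A degenerate
#' all-zero signal yields the uniform mixture and an isotropic ODF, flagged.
#'
#' @param signal_sh A [shell_signal()].
#' @param dictionary A [build_dictionary()] result.
#' @param config A [loresd_config()].
#' @return List with `f`, `p` (an [odf()]) and `degenerate` flag.
#' @export
loresd_init <- function(signal_sh, dictionary,
                        config = loresd_config(lmax = dictionary$lmax)) {
  nf <- dim(dictionary$G)[1L]
  f0 <- rep.int(1 / nf, nf)
  p00 <- 1 / sqrt(4 * pi)
  degenerate <- all(vapply(signal_sh$Sl, function(m) all(m == 0),
                           logical(1))) || signal_sh$S0 == 0
  if (degenerate) {
    p <- c(p00, numeric(sh_ncoef(config$lmax) - 1L))
    return(list(f = f0, p = odf(p, config$lmax, normalised = TRUE),
                degenerate = TRUE))
  }
  ctx <- fit_context(signal_sh, dictionary, config$reg_lambda,
                     config$data_weighting)
  Q <- constraint_basis(config$n_constraint_dirs, config$lmax)
  p <- csd_step(f0, ctx, Q)
  list(f = f0, p = odf(p, config$lmax, normalised = TRUE),
       degenerate = FALSE)
}

#' Joint local response function and ODF estimation for one voxel
#'
#' Jointly estimates the voxel's response function -- a convex mixture of
#' axially symmetric Gaussian kernels on a diffusivity grid -- and its
#' unit-normalised fibre ODF by constrained spherical deconvolution. The
#' coefficient-space misfit plus an anisotropic-response penalty is
#' minimised by sequential least-squares programming (SLSQP, via
#' \pkg{nloptr}) with the analytic gradient, subject to: fractions in
#' `[0, 1]` summing to one, ODF amplitudes nonnegative on a fixed direction
#' set, and the `l = 0` ODF coefficient pinned at `1/sqrt(4*pi)`.
#' Initialisation is the uniform mixture plus a single CSD iteration, so
#' the fit is deterministic given its inputs. Solver failure is reported via
#' `converged = FALSE` with the best iterate, never as an error.
#'
#' @param signal Numeric vector of raw per-volume amplitudes, or a
#'   [shell_signal()].
#' @param scheme An [acquisition_scheme()] (required when `signal` is raw).
#' @param config A [loresd_config()].
#' @param dictionary Optional precomputed [build_dictionary()] (must match
#'   `config`); built on the fly otherwise.
#' @return Object of class `loresd`: mixture fractions `f`, ODF `p`,
#'   response `H`, `rmse` (raw signal space, when the scheme is available),
#'   `objective_value`, `n_iterations`, `converged`, `aic`, `k_params`,
#'   plus the inputs needed by the methods.
#' @seealso [msmt_csd()] for the fixed-response baseline,
#'   [loresd_volume()] for whole-image fitting.
#' @examples
#' sch <- simulation_scheme(ndirs = c(5L, 64L, 64L))
#' cfg <- loresd_config(lmax = 4L, grid = diffusivity_grid(5L))
#' gt <- ground_truth_config()
#' H <- ground_truth_response(gt, sch, lmax = 4L)
#' p <- ground_truth_odf(0, lmax = 4L)
#' fit <- loresd(simulate_signal(H, p, sch), sch, cfg)
#' acc(coef(fit)$odf, p)
#' @export
loresd <- function(signal, scheme = NULL, config = loresd_config(),
                   dictionary = NULL) {
  if (inherits(signal, "shell_signal")) {
    signal_sh <- signal
    raw <- NULL
  } else {
    if (is.null(scheme))
      stop("a raw signal vector needs an acquisition scheme", call. = FALSE)
    raw <- as.numeric(signal)
    signal_sh <- shell_signal(raw, scheme, config$lmax)
  }
  if (is.null(dictionary)) {
    if (!is.null(scheme)) dictionary <- build_dictionary(config$grid, scheme,
                                                         config$lmax)
    else stop("need either a dictionary or a scheme", call. = FALSE)
  }
  ## fit on the S0-normalised signal: the estimate is then exactly
  ## equivariant under signal rescaling (the response carries the scale)
  S0_raw <- signal_sh$S0
  fit_sh <- signal_sh
  if (is.finite(S0_raw) && S0_raw > 0) {
    fit_sh$Sl <- lapply(signal_sh$Sl, function(m) m / S0_raw)
    fit_sh$S0 <- 1
  }
  init <- loresd_init(fit_sh, dictionary, config)
  ctx <- fit_context(fit_sh, dictionary, config$reg_lambda,
                     config$data_weighting)
  Q <- constraint_basis(config$n_constraint_dirs, config$lmax)
  nf <- dim(dictionary$G)[1L]
  nq <- sh_ncoef(config$lmax) - 1L
  p00 <- 1 / sqrt(4 * pi)
  Q2 <- Q[, -1L, drop = FALSE]
  qlow <- -p00 * Q[, 1L]
  fidx <- seq_len(nf)
  qidx <- nf + seq_len(nq)
  ineq_jac <- cbind(matrix(0, nrow(Q), nf), -Q2)
  eq_jac <- matrix(c(rep.int(1, nf), numeric(nq)), 1L)
  x0 <- c(init$f, as_odf_vector(init$p)[-1L])
  res <- nloptr::nloptr(
    x0 = x0,
    eval_f = function(x) obj_value(x[fidx], c(p00, x[qidx]), ctx),
    eval_grad_f = function(x) obj_gradient(x[fidx], c(p00, x[qidx]), ctx),
    lb = c(numeric(nf), rep.int(-Inf, nq)),
    ub = c(rep.int(1, nf), rep.int(Inf, nq)),
    eval_g_ineq = function(x) qlow - drop(Q2 %*% x[qidx]),
    eval_jac_g_ineq = function(x) ineq_jac,
    eval_g_eq = function(x) sum(x[fidx]) - 1,
    eval_jac_g_eq = function(x) eq_jac,
    opts = list(algorithm = "NLOPT_LD_SLSQP", ftol_rel = config$rel_ftol,
                maxeval = 50L * config$max_iter))
  f <- pmin(pmax(res$solution[fidx], 0), 1)
  p <- c(p00, res$solution[qidx])
  feas_eq <- abs(sum(f) - 1)
  feas_ineq <- max(0, -min(drop(Q %*% p)))
  converged <- res$status > 0 && feas_eq <= 1e-6 && feas_ineq <= 1e-6
  H <- assemble_response(f, dictionary, S0_raw)
  H$present <- signal_sh$present
  fit <- structure(list(
    f = mixture_weights(f / sum(f), dictionary$grid),
    p = odf(p, config$lmax, normalised = TRUE),
    H = H,
    objective_value = res$objective,
    n_iterations = res$iterations,
    converged = converged,
    constraint_violation = max(feas_eq, feas_ineq),
    k_params = parameter_count("lore_sd", lmax = config$lmax,
                               grid = config$grid),
    S0 = signal_sh$S0,
    signal_sh = signal_sh,
    config = config,
    scheme = scheme,
    raw_signal = raw,
    method = "loresd"), class = "loresd")
  if (!is.null(raw) && !is.null(scheme)) {
    pred <- predict(fit)
    fit$rmse <- rmse(raw, pred)
    rss <- sum((raw - pred)^2)
    fit$aic <- aic_gaussian(rss, length(raw), fit$k_params)
  } else {
    fit$rmse <- NA_real_
    fit$aic <- NA_real_
  }
  fit
}

#' @export
print.loresd <- function(x, ...) {
  cat("Local response function estimation in spherical deconvolution\n")
  cat(sprintf("  lmax %d, %d mixture nodes, lambda = %g\n",
              x$config$lmax, length(x$f), x$config$reg_lambda))
  cat(sprintf("  converged: %s (%d iterations), objective %.4g\n",
              x$converged, x$n_iterations, x$objective_value))
  if (is.finite(x$rmse))
    cat(sprintf("  RMSE %.4g (S0 = %.4g)\n", x$rmse, x$S0))
  invisible(x)
}

#' @export
coef.loresd <- function(object, ...) {
  list(f = object$f, odf = object$p, response = object$H)
}

#' @export
fitted.loresd <- function(object, ...) predict(object)

#' Predicted signal amplitudes of a fitted voxel model
#'
#' Evaluates the fitted spherical convolution (response times ODF) at the
#' acquisition directions, or at a new scheme.
#'
#' @param object A fitted [loresd()] model.
#' @param scheme Optional replacement [acquisition_scheme()].
#' @param ... Unused.
#' @return Numeric vector of per-volume amplitudes.
#' @export
predict.loresd <- function(object, scheme = NULL, ...) {
  sch <- if (!is.null(scheme)) scheme else object$scheme
  if (is.null(sch))
    stop("no acquisition scheme available for prediction", call. = FALSE)
  H <- if (!is.null(scheme))
    assemble_response(object$f, build_dictionary(object$config$grid, scheme,
                                                 object$config$lmax),
                      object$S0)
  else object$H
  pred_sh <- spherical_convolve(H, object$p)
  shell_signal_amplitudes(pred_sh, sch)
}

#' @export
residuals.loresd <- function(object, ...) {
  if (is.null(object$raw_signal))
    stop("fit was made from SH coefficients; no raw residuals", call. = FALSE)
  object$raw_signal - predict(object)
}

#' @export
summary.loresd <- function(object, ...) {
  cv <- vapply(c("intra", "extra", "free_water", "anisotropy"), function(nm)
    contrast_value(contrast_matrix(nm, object$config$grid), object$f),
    numeric(1))
  out <- list(fit = object, contrasts = cv,
              response_anisotropy_energy =
                sum(object$H$H[, -1L, drop = FALSE]^2))
  class(out) <- "summary.loresd"
  out
}

#' @export
print.summary.loresd <- function(x, ...) {
  print(x$fit)
  cat("  contrasts:\n")
  for (nm in names(x$contrasts))
    cat(sprintf("    %-11s %.4f\n", nm, x$contrasts[[nm]]))
  cat(sprintf("  anisotropic response energy: %.4g\n",
              x$response_anisotropy_energy))
  invisible(x)
}

#' Plot a fitted voxel model
#'
#' Displays the mixture fractions on the triangular diffusivity grid
#' (left) and the fitted ODF profile along elevation (right).
#'
#' @param x A fitted [loresd()] model.
#' @param ... Passed to [graphics::image()].
#' @export
plot.loresd <- function(x, ...) {
  grid <- x$config$grid
  n <- grid$n_per_axis
  M <- matrix(NA_real_, n, n)
  fv <- as_weight_vector(x$f)
  for (j in seq_len(nrow(grid$nodes))) {
    i1 <- match(grid$nodes[j, 1L], grid$axis)
    i2 <- match(grid$nodes[j, 2L], grid$axis)
    M[i1, i2] <- fv[j]
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::image(grid$axis, grid$axis, M,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "axial diffusivity (um^2/ms)",
                  ylab = "radial diffusivity (um^2/ms)",
                  main = "mixture fractions", ...)
  th <- seq(0, pi, length.out = 181)
  amp <- odf_amplitudes(x$p, cbind(sin(th), 0, cos(th)))
  graphics::plot(th * 180 / pi, amp, type = "l",
                 xlab = "elevation (deg)", ylab = "ODF amplitude",
                 main = "fitted ODF profile")
  invisible(x)
}

#' Root mean square error between measured and predicted amplitudes
#'
#' @param measured,predicted Equal-length numeric vectors in raw signal
#'   space.
#' @return Nonnegative scalar.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) == 0L)
    stop("empty input", call. = FALSE)
  if (length(measured) != length(predicted))
    stop("inputs must have equal length", call. = FALSE)
  sqrt(mean((measured - predicted)^2))
}

#' Free-parameter count of the competing models
#'
#' The joint estimator has one ODF coefficient block plus the mixture
#' fractions, minus one sum-to-unity constraint and one ODF normalisation
#' constraint; the fixed-response multi-tissue baseline has the ODF
#' coefficients plus one fraction per isotropic tissue.
#'
#' @param model `"lore_sd"` or `"msmt_csd"`.
#' @param lmax Maximum even SH degree.
#' @param grid A [diffusivity_grid()] (joint model only).
#' @param n_iso Number of isotropic tissues (baseline only).
#' @return Integer parameter count (e.g. 98 and 47 for the defaults).
#' @export
parameter_count <- function(model = c("lore_sd", "msmt_csd"), lmax = 8L,
                            grid = diffusivity_grid(), n_iso = 2L) {
  model <- match.arg(model)
  switch(model,
    lore_sd = sh_ncoef(lmax) + nrow(grid$nodes) - 2L,
    msmt_csd = sh_ncoef(lmax) + as.integer(n_iso))
}

#' Gaussian-residual Akaike Information Criterion
#'
#' `AIC = n * ln(rss / n) + 2k` (Gaussian likelihood with the residual
#' variance profiled out; additive constants drop from any AIC difference).
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n_obs Number of observations (> 0).
#' @param k Free-parameter count.
#' @return AIC value; `-Inf` with a warning when `rss` is exactly 0.
#' @export
aic_gaussian <- function(rss, n_obs, k) {
  stopifnot(rss >= 0, n_obs > 0)
  if (rss == 0) {
    warning("rss = 0: AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * k
}

#' @export
AIC.loresd <- function(object, ..., k = 2) {
  object$aic
}
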