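#' Tissue response set for the fixed-response baseline
#'
#' Bundles an anisotropic white-matter response with named isotropic
#' responses (e.g. grey matter, CSF). All responses must share the shell
#' structure; isotropic responses carry no `l > 0` content.
#'
#' @param wm A [response_function()] with full even-order content.
#' @param iso Named list of isotropic [response_function()]s (only their
#'   `l = 0` column is used; any `l > 0` content is an error).
#' @return Object of class `tissue_responses`.
#' @export
tissue_responses <- function(wm, iso = list()) {
  stopifnot(inherits(wm, "response_function"))
  if (length(iso) && is.null(names(iso)))
    names(iso) <- paste0("iso", seq_along(iso))
  for (nm in names(iso)) {
    r <- iso[[nm]]
    stopifnot(inherits(r, "response_function"))
    if (length(r$bvals) != length(wm$bvals) ||
        max(abs(r$bvals - wm$bvals)) > 1e-6)
      stop("isotropic response '", nm,
           "' does not share the WM shell structure", call. = FALSE)
    if (ncol(r$H) > 1L && max(abs(r$H[, -1L])) > 1e-8)
      stop("isotropic response '", nm, "' has l > 0 content", call. = FALSE)
  }
  structure(list(wm = wm, iso = iso), class = "tissue_responses")
}

#' Fixed-response multi-shell multi-tissue CSD (baseline)
#'
#' Solves the convex least-squares problem: the voxel's per-shell SH
#' coefficients as a white-matter spherical convolution plus isotropic
#' tissue contributions, subject to nonnegative ODF amplitudes on the fixed
#' constraint direction set and nonnegative tissue fractions. Responses are
#' supplied (e.g. ground truth in simulations, or files via
#' [read_response()]); unlike the joint estimator, they are not estimated.
#' The WM ODF here is not unit-normalised: its `l = 0` coefficient carries
#' the WM volume fraction.
#'
#' @param signal Numeric per-volume amplitudes or a [shell_signal()].
#' @param responses A [tissue_responses()] set.
#' @param scheme An [acquisition_scheme()] (required for raw signal input).
#' @param lmax Maximum even SH degree of the ODF.
#' @param n_constraint_dirs Number of ODF nonnegativity directions.
#' @return Object of class `msmt_fit`: `p` (WM ODF, un-normalised),
#'   `fractions` (named per-tissue, including `wm`), `rmse`, `aic`,
#'   `k_params`, `objective_value`.
#' @export
msmt_csd <- function(signal, responses, scheme = NULL, lmax = 8L,
                     n_constraint_dirs = 300L) {
  stopifnot(inherits(responses, "tissue_responses"))
  if (inherits(signal, "shell_signal")) {
    signal_sh <- signal
    raw <- NULL
  } else {
    if (is.null(scheme))
      stop("a raw signal vector needs an acquisition scheme", call. = FALSE)
    raw <- as.numeric(signal)
    signal_sh <- shell_signal(raw, scheme, lmax)
  }
  ls <- sh_degrees(lmax)
  Nl <- sh_nl(lmax)
  niso <- length(responses$iso)
  np <- sh_ncoef(lmax)
  nv <- np + niso
  ## collinearity check between isotropic responses
  if (niso > 1L) {
    iso_cols <- vapply(responses$iso, function(r) r$H[, 1L],
                       numeric(length(responses$wm$bvals)))
    for (a in seq_len(niso - 1L)) for (b in (a + 1L):niso) {
      ca <- iso_cols[, a]; cb <- iso_cols[, b]
      if (sqrt(sum((ca / sqrt(sum(ca^2)) - cb / sqrt(sum(cb^2)))^2)) < 1e-8)
        stop("isotropic responses '", names(responses$iso)[a], "' and '",
             names(responses$iso)[b], "' are collinear", call. = FALSE)
    }
  }
  ## stack rows: one per measured (shell, l, m) coefficient
  rows <- list()
  rhs <- list()
  j <- 0L
  for (i in seq_along(ls)) {
    l <- ls[i]
    idx <- j + seq_len(2L * l + 1L)
    j <- j + 2L * l + 1L
    for (s in which(signal_sh$present[, i])) {
      A <- matrix(0, 2L * l + 1L, nv)
      A[cbind(seq_len(2L * l + 1L), idx)] <- Nl[i] * responses$wm$H[s, i]
      if (l == 0L && niso > 0L) {
        for (t in seq_len(niso))
          A[1L, np + t] <- responses$iso[[t]]$H[s, 1L]
      }
      rows[[length(rows) + 1L]] <- A
      rhs[[length(rhs) + 1L]] <- signal_sh$Sl[[i]][s, ]
    }
  }
  A <- do.call(rbind, rows)
  y <- unlist(rhs)
  Q <- constraint_basis(n_constraint_dirs, lmax)
  Dmat <- 2 * crossprod(A)
  diag(Dmat) <- diag(Dmat) + 1e-12 * max(diag(Dmat))
  Amat <- t(rbind(cbind(Q, matrix(0, nrow(Q), niso)),
                  cbind(matrix(0, niso, np), diag(1, niso))))
  sol <- quadprog::solve.QP(Dmat, 2 * as.numeric(crossprod(A, y)), Amat,
                            numeric(nrow(Q) + niso))
  x <- sol$solution
  p <- x[seq_len(np)]
  fr <- c(wm = p[1L] * sqrt(4 * pi),
          stats::setNames(x[np + seq_len(niso)], names(responses$iso)))
  k <- parameter_count("msmt_csd", lmax = lmax, n_iso = niso)
  fit <- structure(list(
    p = odf(p, lmax, normalised = FALSE),
    fractions = fr,
    objective_value = sum((A %*% x - y)^2),
    k_params = k,
    responses = responses,
    signal_sh = signal_sh,
    scheme = scheme,
    raw_signal = raw,
    method = "msmt_csd"), class = "msmt_fit")
  if (!is.null(raw) && !is.null(scheme)) {
    pred <- predict(fit)
    fit$rmse <- rmse(raw, pred)
    fit$aic <- aic_gaussian(sum((raw - pred)^2), length(raw), k)
  } else {
    fit$rmse <- NA_real_
    fit$aic <- NA_real_
  }
  fit
}

#' @export
print.msmt_fit <- function(x, ...) {
  cat("Fixed-response multi-tissue CSD fit\n")
  cat("  fractions:",
      paste(sprintf("%s = %.4g", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  if (is.finite(x$rmse)) cat(sprintf("  RMSE %.4g\n", x$rmse))
  invisible(x)
}

#' @export
coef.msmt_fit <- function(object, ...) {
  list(odf = object$p, fractions = object$fractions)
}

#' Predicted amplitudes of a baseline fit
#'
#' @param object An [msmt_csd()] fit.
#' @param scheme Optional replacement [acquisition_scheme()].
#' @param ... Unused.
#' @return Numeric vector of per-volume amplitudes.
#' @export
predict.msmt_fit <- function(object, scheme = NULL, ...) {
  sch <- if (!is.null(scheme)) scheme else object$scheme
  if (is.null(sch)) stop("no acquisition scheme available", call. = FALSE)
  wm <- object$responses$wm
  wm$present <- object$signal_sh$present
  sig <- spherical_convolve(wm, object$p)
  for (t in seq_along(object$responses$iso)) {
    frac <- object$fractions[[names(object$responses$iso)[t]]]
    sig$Sl[[1L]][, 1L] <- sig$Sl[[1L]][, 1L] +
      frac * object$responses$iso[[t]]$H[, 1L]
  }
  shell_signal_amplitudes(sig, sch)
}

#' @export
residuals.msmt_fit <- function(object, ...) {
  if (is.null(object$raw_signal))
    stop("fit was made from SH coefficients; no raw residuals", call. = FALSE)
  object$raw_signal - predict(object)
}

#' Read a multi-shell response function from a text file
#'
#' The standard multi-shell response format: one row per shell, columns are
#' the even-order zonal coefficients (`l = 0, 2, ...`); isotropic responses
#' have a single column.
#'
#' @param path File path.
#' @param bvals Optional shell b-values to attach (ms/um^2).
#' @return A [response_function()].
#' @export
read_response <- function(path, bvals = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "[[:space:],]+")[[1]]))
    if (anyNA(v)) stop("response file '", path,
                       "': non-numeric entry on line ", i, call. = FALSE)
    v
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("response file '", path, "': ragged row on line ",
         which(ncols != ncols[1L])[1L], call. = FALSE)
  H <- do.call(rbind, rows)
  if (is.null(bvals)) bvals <- seq_len(nrow(H)) - 1
  response_function(H, bvals = bvals)
}

#' Write a response function to the multi-shell text format
#'
#' @param response A [response_function()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response <- function(response, path) {
  stopifnot(inherits(response, "response_function"))
  utils::write.table(format(response$H, digits = 17), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
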