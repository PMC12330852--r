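#' ODF coefficient vector
#'
#' A fibre orientation distribution function represented by its real
#' even-order SH coefficients up to `lmax`. When `normalised` is `TRUE` the
#' `l = 0` coefficient equals `1/sqrt(4*pi)` so the ODF integrates to one
#' over the sphere.
#'
#' @param p Numeric coefficient vector of length `sh_ncoef(lmax)`.
#' @param lmax Maximum even SH degree; inferred from `length(p)` if missing.
#' @param normalised Logical; is the unit-normalisation constraint active?
#' @return Object of class `odf`.
#' @export
odf <- function(p, lmax = NULL, normalised = FALSE) {
  p <- as.numeric(p)
  if (is.null(lmax)) {
    lmax <- (sqrt(8 * length(p) + 1) - 3) / 2
    if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
      stop("length(p) is not a valid even-order SH coefficient count",
           call. = FALSE)
    lmax <- as.integer(round(lmax))
  }
  if (length(p) != sh_ncoef(lmax))
    stop("length(p) does not match sh_ncoef(lmax)", call. = FALSE)
  if (normalised && abs(p[1L] - 1 / sqrt(4 * pi)) > 1e-12)
    stop("normalised ODF must have l = 0 coefficient 1/sqrt(4*pi)",
         call. = FALSE)
  structure(p, lmax = lmax, normalised = normalised, class = "odf")
}

as_odf_vector <- function(x) {
  if (inherits(x, "odf")) as.numeric(unclass(x)) else as.numeric(x)
}

#' @export
print.odf <- function(x, ...) {
  cat(sprintf("ODF: lmax = %d (%d coefficients)%s\n", attr(x, "lmax"),
              length(x), if (isTRUE(attr(x, "normalised")))
                ", unit-normalised" else ""))
  invisible(x)
}

#' Evaluate ODF amplitudes on a direction set
#'
#' @param x An [odf()].
#' @param directions n x 3 unit vectors.
#' @return Numeric vector of amplitudes.
#' @export
odf_amplitudes <- function(x, directions) {
  lmax <- attr(x, "lmax")
  if (is.null(lmax)) lmax <- odf(as.numeric(x)) |> attr("lmax")
  drop(sh_basis_matrix(directions, lmax) %*% as_odf_vector(x))
}

#' Diffusion acquisition scheme
#'
#' Groups the per-volume b-values and gradient directions of a diffusion
#' acquisition into discrete shells. b-values may be given in s/mm^2 (the
#' usual scanner convention) or ms/um^2; values are stored in ms/um^2
#' (1000 s/mm^2 = 1 ms/um^2). Input is treated as s/mm^2 when the largest
#' b-value exceeds 50, the shell-merging tolerance. Volumes with b below
#' 0.05 ms/um^2 (50 s/mm^2) form the b = 0 shell; other volumes join a shell
#' when within 0.1 ms/um^2 (100 s/mm^2) of its centre, absorbing scanner
#' jitter.
#'
#' @param bvals Numeric vector of per-volume b-values.
#' @param bvecs n x 3 matrix of gradient directions (unit norm for b > 0;
#'   zero rows are accepted for b = 0 volumes).
#' @param b0_threshold b-value (ms/um^2) below which a volume counts as b = 0.
#' @param shell_tolerance Maximum distance (ms/um^2) from a shell centre.
#' @return Object of class `acquisition_scheme` with elements `bvals`,
#'   `bvecs`, `shell_b` (representative b per shell), `shell_index`
#'   (per-volume shell id), `shell_dirs`, `per_shell_lmax`.
#' @export
acquisition_scheme <- function(bvals, bvecs, b0_threshold = 0.05,
                               shell_tolerance = 0.1) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("gradient table has %d rows but %d b-values",
                 nrow(bvecs), length(bvals)), call. = FALSE)
  if (any(bvals < 0)) stop("b-values must be >= 0", call. = FALSE)
  if (max(bvals) > 50) bvals <- bvals / 1000   # s/mm^2 -> ms/um^2
  nrm <- sqrt(rowSums(bvecs^2))
  dwi <- bvals > b0_threshold
  if (any(dwi & abs(nrm - 1) > 1e-4))
    stop("gradient directions must be unit vectors for b > 0 volumes",
         call. = FALSE)
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  ## greedy shell grouping
  shell_index <- integer(length(bvals))
  centres <- numeric(0)
  for (b in sort(unique(bvals))) {
    hit <- which(abs(centres - b) <= shell_tolerance + 1e-12)
    if (b <= b0_threshold) {
      if (length(centres) == 0L || centres[1L] > b0_threshold) {
        centres <- c(0, centres)
        shell_index[shell_index > 0L] <- shell_index[shell_index > 0L] + 1L
      }
      shell_index[bvals == b] <- 1L
    } else if (length(hit)) {
      shell_index[bvals == b] <- hit[1L]
    } else {
      centres <- c(centres, b)
      shell_index[bvals == b] <- length(centres)
    }
  }
  shell_b <- vapply(seq_along(centres), function(s) {
    if (centres[s] <= b0_threshold) 0 else mean(bvals[shell_index == s])
  }, numeric(1))
  shell_dirs <- lapply(seq_along(centres), function(s)
    bvecs[shell_index == s, , drop = FALSE])
  per_shell_lmax <- vapply(seq_along(centres), function(s) {
    if (shell_b[s] <= b0_threshold) return(0L)
    n <- sum(shell_index == s)
    lm <- 0L
    while (sh_ncoef(lm + 2L) <= n) lm <- lm + 2L
    lm
  }, integer(1))
  structure(list(bvals = bvals, bvecs = bvecs, shell_b = shell_b,
                 shell_index = shell_index, shell_dirs = shell_dirs,
                 per_shell_lmax = per_shell_lmax,
                 b0_threshold = b0_threshold),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("Acquisition scheme: %d volumes, %d shells\n",
              length(x$bvals), length(x$shell_b)))
  for (s in seq_along(x$shell_b))
    cat(sprintf("  b = %.3g ms/um^2: %d directions (lmax %d)\n",
                x$shell_b[s], sum(x$shell_index == s), x$per_shell_lmax[s]))
  invisible(x)
}

#' Simulation acquisition scheme
#'
#' The default scheme used by the voxel-level simulations: b = 0, 1000,
#' 2000 s/mm^2 with 5, 128 and 128 quasi-uniform directions. Directions are
#' deterministic for a given seed.
#'
#' @param bvals Shell b-values in ms/um^2.
#' @param ndirs Directions per shell.
#' @param seed Seed for [uniform_directions()].
#' @return An [acquisition_scheme()].
#' @export
simulation_scheme <- function(bvals = c(0, 1, 2), ndirs = c(5L, 128L, 128L),
                              seed = 1L) {
  stopifnot(length(bvals) == length(ndirs))
  dirs <- do.call(rbind, lapply(seq_along(ndirs), function(s)
    uniform_directions(ndirs[s], seed = seed + s - 1L)))
  acquisition_scheme(rep.int(bvals, ndirs), dirs)
}

new_shell_signal <- function(Sl, present, S0, lmax, bvals) {
  structure(list(Sl = Sl, present = present, S0 = S0, lmax = lmax,
                 bvals = bvals),
            class = "shell_signal")
}

#' Per-shell SH representation of a voxel's signal
#'
#' Fits each shell's measured amplitudes with the SH basis up to that
#' shell's supported degree (capped at `lmax`), and records the mean raw
#' b = 0 amplitude `S0`. Coefficient rows exist only for `(shell, l)` pairs
#' with `l` at or below the shell's degree. A negative `S0` is accepted but
#' flagged with a warning.
#'
#' @param amplitudes Numeric vector, one raw signal value per volume.
#' @param scheme An [acquisition_scheme()].
#' @param lmax Maximum even SH degree of the representation.
#' @return A `shell_signal` object: list of per-degree coefficient matrices
#'   (`shells x (2l+1)`), presence mask, `S0`, `lmax`, shell b-values.
#' @export
shell_signal <- function(amplitudes, scheme, lmax = 8L) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  check_lmax(lmax)
  if (length(amplitudes) != length(scheme$bvals))
    stop(sprintf("signal has %d volumes but the scheme has %d",
                 length(amplitudes), length(scheme$bvals)), call. = FALSE)
  ls <- sh_degrees(lmax)
  nshell <- length(scheme$shell_b)
  Sl <- lapply(ls, function(l) matrix(0, nshell, 2L * l + 1L))
  present <- matrix(FALSE, nshell, length(ls))
  for (s in seq_len(nshell)) {
    sel <- scheme$shell_index == s
    lm <- min(scheme$per_shell_lmax[s], lmax)
    cf <- fit_shell_sh(amplitudes[sel], scheme$shell_dirs[[s]], lm)
    j <- 0L
    for (i in seq_along(ls)) {
      l <- ls[i]
      if (l > lm) break
      Sl[[i]][s, ] <- cf[j + seq_len(2L * l + 1L)]
      present[s, i] <- TRUE
      j <- j + 2L * l + 1L
    }
  }
  b0 <- scheme$shell_b <= scheme$b0_threshold
  S0 <- if (any(b0)) mean(amplitudes[scheme$shell_index %in% which(b0)])
        else mean(amplitudes[scheme$shell_index == which.min(scheme$shell_b)])
  if (S0 < 0) warning("negative mean b = 0 amplitude (S0)", call. = FALSE)
  new_shell_signal(Sl = Sl, present = present, S0 = S0, lmax = lmax,
                  bvals = scheme$shell_b)
}

#' @export
print.shell_signal <- function(x, ...) {
  cat(sprintf("Shell signal SH: %d shells, lmax %d, S0 = %.4g\n",
              length(x$bvals), x$lmax, x$S0))
  invisible(x)
}

#' Predicted amplitudes of a shell-signal SH representation
#'
#' Evaluates the per-shell SH coefficient rows at the acquisition
#' directions, volume by volume.
#'
#' @param signal_sh A `shell_signal`.
#' @param scheme The [acquisition_scheme()] the signal was fitted on.
#' @return Numeric vector, one amplitude per volume.
#' @export
shell_signal_amplitudes <- function(signal_sh, scheme) {
  stopifnot(inherits(signal_sh, "shell_signal"))
  ls <- sh_degrees(signal_sh$lmax)
  out <- numeric(length(scheme$bvals))
  for (s in seq_along(scheme$shell_b)) {
    sel <- scheme$shell_index == s
    pres <- signal_sh$present[s, ]
    lm <- max(c(0L, ls[pres]))
    cf <- unlist(lapply(which(pres), function(i) signal_sh$Sl[[i]][s, ]))
    Y <- sh_basis_matrix(scheme$shell_dirs[[s]], lm)
    out[sel] <- drop(Y %*% cf)
  }
  out
}
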