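#' Fit the joint estimator to every voxel of a masked volume
#'
#' Applies [loresd()] independently to each voxel inside the mask,
#' optionally in parallel (forked workers). Voxels are self-contained, so
#' the result is independent of thread count and visit order.
#'
#' @param dwi 4D numeric array (x, y, z, volumes).
#' @param mask 3D logical/numeric array matching the spatial dimensions.
#' @param scheme An [acquisition_scheme()] with one entry per volume.
#' @param config A [loresd_config()]; `config$n_threads` sets the worker
#'   count.
#' @return Object of class `loresd_volume`: 4D arrays `odf`
#'   (`sh_ncoef(lmax)` coefficients) and `mixture` (one fraction per grid
#'   node), 3D arrays `rmse`, `converged`, and the four contrast maps
#'   `intra`, `extra`, `free_water`, `anisotropy`; voxels outside the mask
#'   are zero.
#' @export
loresd_volume <- function(dwi, mask, scheme, config = loresd_config()) {
  dims <- dim(dwi)
  if (length(dims) != 4L)
    stop("dwi must be a 4D array", call. = FALSE)
  if (!all(dim(mask) == dims[1:3]))
    stop(sprintf("mask dimensions (%s) do not match dwi (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(dims[1:3], collapse = "x")), call. = FALSE)
  if (dims[4L] != length(scheme$bvals))
    stop(sprintf("dwi has %d volumes but the scheme has %d",
                 dims[4L], length(scheme$bvals)), call. = FALSE)
  vox <- which(mask != 0)
  nc <- sh_ncoef(config$lmax)
  nf <- nrow(config$grid$nodes)
  out <- list(
    odf = array(0, c(dims[1:3], nc)),
    mixture = array(0, c(dims[1:3], nf)),
    rmse = array(0, dims[1:3]),
    converged = array(FALSE, dims[1:3]),
    intra = array(0, dims[1:3]), extra = array(0, dims[1:3]),
    free_water = array(0, dims[1:3]), anisotropy = array(0, dims[1:3]))
  if (length(vox) == 0L) {
    out$config <- config
    class(out) <- "loresd_volume"
    return(out)
  }
  dict <- build_dictionary(config$grid, scheme, config$lmax)
  W <- lapply(c(intra = "intra", extra = "extra", free_water = "free_water",
                anisotropy = "anisotropy"),
              contrast_matrix, grid = config$grid)
  nvol <- prod(dims[1:3])
  sigmat <- matrix(dwi, nvol, dims[4L])
  fit_one <- function(v) {
    fit <- loresd(sigmat[v, ], scheme, config, dict)
    list(p = as_odf_vector(fit$p), f = as_weight_vector(fit$f),
         rmse = fit$rmse, converged = fit$converged,
         contrasts = vapply(W, contrast_value, numeric(1), f = fit$f))
  }
  res <- if (config$n_threads > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(vox, fit_one, mc.cores = config$n_threads,
                       mc.preschedule = TRUE)
  else lapply(vox, fit_one)
  for (k in seq_along(vox)) {
    v <- vox[k]
    r <- res[[k]]
    out$odf[v + nvol * (seq_len(nc) - 1L)] <- r$p
    out$mixture[v + nvol * (seq_len(nf) - 1L)] <- r$f
    out$rmse[v] <- r$rmse
    out$converged[v] <- r$converged
    out$intra[v] <- r$contrasts[["intra"]]
    out$extra[v] <- r$contrasts[["extra"]]
    out$free_water[v] <- r$contrasts[["free_water"]]
    out$anisotropy[v] <- r$contrasts[["anisotropy"]]
  }
  out$config <- config
  class(out) <- "loresd_volume"
  out
}

#' @export
print.loresd_volume <- function(x, ...) {
  nfit <- sum(x$rmse > 0 | x$converged)
  cat(sprintf("Volume fit: %d voxels, %d converged; lmax %d, %d nodes\n",
              nfit, sum(x$converged), x$config$lmax,
              nrow(x$config$grid$nodes)))
  invisible(x)
}
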