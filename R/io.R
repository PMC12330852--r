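#' Read a diffusion-weighted image with its gradient table
#'
#' Loads a 4D NIfTI image and aligns it with a gradient table given either
#' as an FSL `bvals`/`bvecs` pair or as an MRtrix-style 4-column text file
#' (`x y z b`, one row per volume). b-values are converted to ms/um^2 and
#' volumes grouped into shells; the NIfTI header is retained for output
#' writing.
#'
#' @param image_path Path to a `.nii`/`.nii.gz` file.
#' @param grad_path Either one path (MRtrix table) or
#'   `c(bvals_path, bvecs_path)` (FSL pair).
#' @return List with `data` (4D array), `scheme`
#'   ([acquisition_scheme()]) and `header` (the RNifti image for affine
#'   reuse).
#' @export
read_dwi <- function(image_path, grad_path) {
  img <- RNifti::readNifti(image_path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  gt <- read_gradients(grad_path)
  if (nrow(gt$bvecs) != dim(data)[4L])
    stop(sprintf("image has %d volumes but the gradient table has %d rows",
                 dim(data)[4L], nrow(gt$bvecs)), call. = FALSE)
  zero <- sqrt(rowSums(gt$bvecs^2)) < 1e-6
  if (any(zero))
    gt$bvecs[zero, ] <- matrix(c(0, 0, 1), sum(zero), 3L, byrow = TRUE)
  scheme <- acquisition_scheme(gt$bvals, gt$bvecs)
  list(data = data, scheme = scheme, header = img)
}

#' Read a gradient table
#'
#' @param grad_path One path (MRtrix 4-column `x y z b`) or two paths
#'   (FSL `bvals` then `bvecs`).
#' @return List with `bvals` (per volume) and `bvecs` (n x 3).
#' @export
read_gradients <- function(grad_path) {
  if (length(grad_path) == 2L) {
    bvals <- scan(grad_path[1L], quiet = TRUE)
    bv <- unname(as.matrix(utils::read.table(grad_path[2L])))
    if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
    if (ncol(bv) != 3L)
      stop("bvecs file must be 3 x n or n x 3", call. = FALSE)
    if (nrow(bv) != length(bvals))
      stop(sprintf("bvals has %d entries but bvecs has %d rows",
                   length(bvals), nrow(bv)), call. = FALSE)
    return(list(bvals = bvals, bvecs = bv))
  }
  tab <- unname(as.matrix(utils::read.table(grad_path)))
  if (ncol(tab) != 4L)
    stop("unknown gradient dialect: expected an MRtrix 4-column table ",
         "(x y z b) or an FSL bvals/bvecs pair", call. = FALSE)
  list(bvals = tab[, 4L], bvecs = tab[, 1:3, drop = FALSE])
}

#' Write fitted maps as NIfTI images with sidecar metadata
#'
#' Writes the coefficient images of a [loresd_volume()] fit (ODF, mixture,
#' RMSE and the contrast maps) next to each other, carrying the affine of a
#' reference image, plus a plain-text sidecar documenting the coefficient
#' and grid-node orderings.
#'
#' @param fit A [loresd_volume()] result.
#' @param dir Output directory (created if needed).
#' @param reference Optional RNifti image (from [read_dwi()]) whose header
#'   supplies the affine.
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_maps <- function(fit, dir, reference = NULL, prefix = "loresd") {
  stopifnot(inherits(fit, "loresd_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list(odf = fit$odf, mixture = fit$mixture, rmse = fit$rmse,
               intra = fit$intra, extra = fit$extra,
               free_water = fit$free_water, anisotropy = fit$anisotropy)
  paths <- character(0)
  for (nm in names(maps)) {
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    img <- maps[[nm]]
    if (!is.null(reference)) {
      tmpl <- RNifti::asNifti(reference)
      img <- RNifti::asNifti(img, reference = tmpl)
    }
    RNifti::writeNifti(img, path)
    paths[nm] <- path
  }
  sidecar <- file.path(dir, sprintf("%s_layout.txt", prefix))
  grid <- fit$config$grid
  writeLines(c(
    sprintf("odf: %d real symmetric SH coefficients, degrees %s,",
            sh_ncoef(fit$config$lmax),
            paste(sh_degrees(fit$config$lmax), collapse = " ")),
    "     within each degree m = -l..l (MRtrix ordering)",
    sprintf("mixture: %d diffusivity-grid nodes, ordered by",
            nrow(grid$nodes)),
    "     axial then radial diffusivity:",
    apply(format(grid$nodes, digits = 6), 1L, paste, collapse = " ")),
    sidecar)
  paths["layout"] <- sidecar
  invisible(paths)
}

#' Run manifest
#'
#' A machine-readable record of a run: configuration snapshot, input file
#' digests, seed, package version and timestamps. Re-running with an
#' identical manifest reproduces identical outputs.
#'
#' @param config A [loresd_config()].
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param path Where to write the JSON manifest.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, inputs = character(0), path,
                           extra = list()) {
  cfgl <- unclass(config)
  cfgl$grid <- list(n_per_axis = config$grid$n_per_axis,
                    range = config$grid$range)
  man <- c(list(
    package = "loresd",
    version = as.character(utils::packageVersion("loresd")),
    seed = config$seed,
    config = cfgl,
    inputs = as.list(tools::md5sum(inputs)),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

#' Parse a key=value configuration file
#'
#' Minimal INI-style parser: `[section]` headers, `key = value` pairs,
#' `#` comments. Values are auto-converted to numeric where possible;
#' comma-separated values become vectors.
#'
#' @param path File path.
#' @return Nested named list (one element per section; top-level keys go in
#'   `$global`).
#' @export
read_config_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) parts <- num
    if (identical(parts, "true")) parts <- TRUE
    if (identical(parts, "false")) parts <- FALSE
    out[[section]][[key]] <- parts
  }
  out
}
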