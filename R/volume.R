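#' Write a phantom to NIfTI volumes with a JSON sidecar
#'
#' One pair of 4D NIfTI files (real and imaginary parts, phase increments on
#' the 4th axis) per setting, the ground-truth parameter maps, the B1+ and
#' off-resonance fields, and a sidecar JSON holding the protocol and the
#' file layout.
#'
#' @param phantom an `mt_phantom`.
#' @param dir output directory (created if missing).
#' @return the sidecar path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (i in seq_along(phantom$volumes)) {
    re_f <- file.path(dir, sprintf("setting%02d_real.nii.gz", i))
    im_f <- file.path(dir, sprintf("setting%02d_imag.nii.gz", i))
    RNifti::writeNifti(Re(phantom$volumes[[i]]), re_f)
    RNifti::writeNifti(Im(phantom$volumes[[i]]), im_f)
    files[[i]] <- list(real = basename(re_f), imag = basename(im_f))
  }
  for (p in names(phantom$truth))
    RNifti::writeNifti(phantom$truth[[p]],
                       file.path(dir, sprintf("truth_%s.nii.gz", p)))
  RNifti::writeNifti(phantom$b1, file.path(dir, "b1.nii.gz"))
  RNifti::writeNifti(phantom$df0, file.path(dir, "truth_df0.nii.gz"))
  sidecar <- file.path(dir, "phantom.json")
  write_protocol(phantom$protocol, file.path(dir, "protocol.json"))
  jsonlite::write_json(list(protocol = "protocol.json", volumes = files,
                            b1 = "b1.nii.gz", shape = phantom$spec$shape),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Load a set of complex SSFP volumes
#'
#' @param paths a list with one entry per setting; each entry is a list with
#'   elements `real`/`imag` (or `mag`/`phase` when `format = "magphase"`)
#'   naming 4D NIfTI files whose 4th axis holds the phase increments.
#' @param protocol an [mt_protocol()]; the 4th-axis length of every volume
#'   must match the setting's phase-increment count.
#' @param b1 optional path to (or array of) a relative transmit field map.
#' @param mask optional logical array restricting the fit.
#' @param format `"reim"` for real/imaginary pairs, `"magphase"` for
#'   magnitude/phase (phase in radians).
#' @return an object of class `volume_set`: complex arrays `data` (one per
#'   setting), `b1`, `mask`, `protocol`, and the reference NIfTI `header`.
#' @export
load_volume_set <- function(paths, protocol, b1 = NULL, mask = NULL,
                            format = c("reim", "magphase")) {
  format <- match.arg(format)
  if (length(paths) != length(protocol$settings))
    stop_mtellipse("one volume pair per protocol setting required",
                   "invalid_volumes")
  header <- NULL; shape <- NULL
  data <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    nm <- if (format == "reim") c("real", "imag") else c("mag", "phase")
    v1 <- RNifti::readNifti(p[[nm[1]]])
    v2 <- RNifti::readNifti(p[[nm[2]]])
    if (is.null(header)) { header <- RNifti::niftiHeader(v1); shape <- dim(v1) }
    for (v in list(v1, v2)) if (!identical(dim(v), shape))
      stop_mtellipse(sprintf(
        "volume grid mismatch for setting %d: expected %s, got %s (%s)",
        i, paste(shape, collapse = "x"), paste(dim(v), collapse = "x"),
        paste(unlist(p), collapse = ", ")), "grid_mismatch")
    n_inc <- length(protocol$settings[[i]]$phase_increments)
    if (length(shape) != 4 || shape[4] != n_inc)
      stop_mtellipse(sprintf(
        "setting %d: 4th axis (%s) does not match %d phase increments",
        i, paste(dim(v1), collapse = "x"), n_inc), "increment_mismatch")
    data[[i]] <- if (format == "reim")
      array(complex(real = v1, imaginary = v2), dim = shape)
    else
      array(complex(modulus = v1, argument = v2), dim = shape)
  }
  grid <- shape[1:3]
  if (!is.null(b1)) {
    if (is.character(b1)) b1 <- RNifti::readNifti(b1)
    if (!identical(dim(b1)[1:3], grid))
      stop_mtellipse("B1+ map grid does not match the volumes",
                     "grid_mismatch")
  }
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  structure(list(data = data, b1 = b1, mask = mask, protocol = protocol,
                 header = header, shape = grid),
            class = "volume_set")
}

#' Load a phantom directory written by [write_phantom()]
#'
#' @param dir the phantom directory.
#' @return a `volume_set`.
#' @export
load_phantom_dir <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "phantom.json"),
                            simplifyVector = FALSE)
  protocol <- read_protocol(file.path(dir, sc$protocol))
  paths <- lapply(sc$volumes, function(v)
    list(real = file.path(dir, v$real), imag = file.path(dir, v$imag)))
  b1 <- file.path(dir, sc$b1)
  load_volume_set(paths, protocol, b1 = if (file.exists(b1)) b1)
}

#' Voxelwise two-stage qMT fit over a volume set
#'
#' Runs the per-ellipse stage-1 fit for every setting and the stage-2 MT fit
#' in each voxel of the mask.  Off-resonance is reported in Hz as
#' `df0 = psi_i / (2*pi*TR_i)` averaged over settings.  Per-voxel failures
#' are flagged in the `status` map (0 = OK, 1 = outside mask, 2 = stage-1
#' failure, 3 = stage-2 failure) and never abort the volume.
#'
#' @param vs a `volume_set`.
#' @param sentinel value written into masked-out / failed voxels.
#' @param progress print progress every 500 voxels?
#' @return an object of class `qmt_maps`: parameter maps (`m0f`, `fb`,
#'   `kbf`, `t1f`, `t2f`, `df0`, `phi_rf`), per-setting `rmse` and
#'   `rel_rmse` 4D arrays, `kbf_at_bound`, `status`, and the input `header`.
#' @export
fit_volume <- function(vs, sentinel = NA_real_, progress = FALSE) {
  grid <- vs$shape
  settings <- vs$protocol$settings
  m <- length(settings)
  trs <- vapply(settings, `[[`, numeric(1), "tr")
  nv <- prod(grid)
  idx_fit <- which(vs$mask)
  if (!length(idx_fit))
    stop_mtellipse("mask is empty", "invalid_input")

  mk <- function() array(sentinel, dim = grid)
  maps <- list(m0f = mk(), fb = mk(), kbf = mk(), t1f = mk(), t2f = mk(),
               df0 = mk(), phi_rf = mk())
  rmse <- array(sentinel, dim = c(grid, m))
  rel_rmse <- array(sentinel, dim = c(grid, m))
  kbf_at_bound <- array(FALSE, dim = grid)
  status <- array(1L, dim = grid)

  for (vi in seq_along(idx_fit)) {
    v <- idx_fit[vi]
    b1v <- if (is.null(vs$b1)) 1 else as.numeric(vs$b1[v])
    fits <- vector("list", m)
    ok <- TRUE
    for (i in seq_len(m)) {
      s <- settings[[i]]
      n_inc <- length(s$phase_increments)
      samples <- vs$data[[i]][v + (seq_len(n_inc) - 1L) * nv]
      fits[[i]] <- tryCatch(
        fit_ellipse(samples, s$phase_increments, s$tr, s$alpha),
        error = function(e) NULL)
      if (is.null(fits[[i]])) { ok <- FALSE; break }
    }
    if (!ok) { status[v] <- 2L; next }
    for (i in seq_len(m)) {
      rmse[v + (i - 1L) * nv] <- fits[[i]]$rmse
      rel_rmse[v + (i - 1L) * nv] <- fits[[i]]$rel_rmse
    }
    a <- vapply(fits, function(f) f$params$a, numeric(1))
    me <- vapply(fits, function(f) f$params$me, numeric(1))
    b <- vapply(fits, function(f) f$params$b, numeric(1))
    psih <- vapply(fits, function(f) f$params$psi, numeric(1))
    phih <- vapply(fits, function(f) f$params$phi_rf, numeric(1))
    q <- tryCatch({
      t2f <- estimate_t2f(a, trs)
      fit_qmt(me, b, settings, t2f, b1 = b1v, g0 = vs$protocol$g0)
    }, error = function(e) NULL)
    if (is.null(q)) { status[v] <- 3L; next }
    maps$m0f[v] <- q$m0f; maps$fb[v] <- q$fb; maps$kbf[v] <- q$kbf
    maps$t1f[v] <- q$t1f; maps$t2f[v] <- q$t2f
    maps$df0[v] <- mean(psih / (2 * pi * trs) * 1000)   # rad/TR -> Hz
    maps$phi_rf[v] <- mean(phih)
    kbf_at_bound[v] <- q$hit_bounds[["kbf"]]
    status[v] <- 0L
    if (progress && vi %% 500 == 0)
      message(sprintf("  voxel %d / %d", vi, length(idx_fit)))
  }
  structure(list(maps = maps, rmse = rmse, rel_rmse = rel_rmse,
                 kbf_at_bound = kbf_at_bound, status = status,
                 header = vs$header),
            class = "qmt_maps")
}

#' Write fitted parameter maps as NIfTI
#'
#' The input image header (affine and orientation) is propagated unchanged.
#'
#' @param maps a `qmt_maps` object from [fit_volume()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_qmt_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- maps$header
  wr <- function(x, name) {
    img <- RNifti::asNifti(x, reference = tpl)
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  for (p in names(maps$maps)) wr(maps$maps[[p]], p)
  wr(maps$rmse, "rmse")
  wr(maps$rel_rmse, "rel_rmse")
  wr(maps$status, "status")
  wr(maps$kbf_at_bound * 1L, "kbf_at_bound")
  invisible(dir)
}
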