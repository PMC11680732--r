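#' 4-D CEST image stack
#'
#' Container for a CEST acquisition: a 4-D magnitude array `data`
#' (x, y, slice, offset), the matching 3-D `m0` normalization volume
#' (acquired far off-resonance), an optional low-power 4-D `wassr` stack with
#' its own offsets, the spectral axis, named 3-D logical masks (at least
#' `brain`; `corpus_callosum` switches the white-matter model during
#' fitting), and the voxel size.
#'
#' @param data 4-D numeric array (x, y, slice, offset).
#' @param m0 3-D array matching the spatial dimensions.
#' @param offsets_ppm Spectral axis, length `dim(data)[4]`.
#' @param masks Named list of 3-D logical arrays.
#' @param wassr Optional 4-D low-power stack.
#' @param wassr_offsets_ppm Spectral axis of `wassr`.
#' @param voxel_mm Voxel size (mm).
#' @return A list of class `cest_stack`.
#' @export
cest_stack <- function(data, m0, offsets_ppm, masks = list(), wassr = NULL,
                       wassr_offsets_ppm = NULL, voxel_mm = 0.15) {
  if (length(dim(data)) != 4L) abort("`data` must be a 4-D array.")
  sp <- dim(data)[1:3]
  if (!identical(dim(m0), sp)) abort("`m0` spatial dimensions must match `data`.")
  if (length(offsets_ppm) != dim(data)[4])
    abort("`offsets_ppm` length must match the 4th dimension of `data`.")
  for (nm in names(masks))
    if (!identical(dim(masks[[nm]]), sp))
      abort(sprintf("mask '%s' dimensions must match `data`.", nm))
  if (!is.null(wassr)) {
    if (length(dim(wassr)) != 4L || !identical(dim(wassr)[1:3], sp))
      abort("`wassr` spatial dimensions must match `data`.")
    if (is.null(wassr_offsets_ppm) ||
        length(wassr_offsets_ppm) != dim(wassr)[4])
      abort("`wassr_offsets_ppm` must match the wassr stack.")
  }
  structure(list(data = data, m0 = m0, offsets_ppm = as.numeric(offsets_ppm),
                 masks = masks, wassr = wassr,
                 wassr_offsets_ppm = wassr_offsets_ppm, voxel_mm = voxel_mm),
            class = "cest_stack")
}

#' @export
print.cest_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cest_stack> %d x %d x %d voxels, %d offsets [%g, %g] ppm\n",
              d[1], d[2], d[3], d[4], min(x$offsets_ppm), max(x$offsets_ppm)))
  cat("  masks:", if (length(x$masks)) paste(names(x$masks), collapse = ", ")
      else "(none)", "\n")
  cat("  wassr:", if (is.null(x$wassr)) "absent" else "present", "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# multilinear SVD denoising
# ---------------------------------------------------------------------------

unfold3 <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(x, perm), nrow = d[mode])
}

fold3 <- function(m, mode, d) {
  perm <- c(mode, setdiff(1:3, mode))
  aperm(array(m, d[perm]), order(perm))
}

# project a 3-way tensor onto the span of the leading left singular vectors
# of each unfolding (truncated higher-order SVD)
hosvd_truncate <- function(x, ranks) {
  d <- dim(x)
  us <- lapply(1:3, function(mode) {
    u <- svd(unfold3(x, mode), nu = min(ranks[mode], d[mode]))$u
    u
  })
  y <- x
  for (mode in 1:3) {
    p <- us[[mode]] %*% Conj(t(us[[mode]]))
    y <- fold3(p %*% unfold3(y, mode), mode, d)
  }
  y
}

#' Multilinear SVD denoising of a CEST stack
#'
#' Per slice, transforms each offset image to the spatial-frequency domain
#' (unitary 2-D DFT), truncates the 3-way tensor
#' (k_x, k_y, offset) to the stated multilinear ranks by higher-order SVD,
#' and transforms back. The conventional core size for full-resolution
#' acquisitions is 30 x 30 spatial by 10 spectral. The retained fraction of
#' tensor energy (squared higher-order singular values) is reported per
#' slice in the attribute `"energy"`.
#'
#' @param stack A [cest_stack()].
#' @param core Integer vector `c(spatial, spatial, spectral)` of multilinear
#'   ranks; must not exceed the corresponding dimensions.
#' @param denoise_wassr Also denoise the WASSR stack at the same spatial
#'   ranks (spectral rank capped at its offset count).
#' @return The denoised stack, with attribute `"energy"`.
#' @export
mlsvd_denoise <- function(stack, core = c(30, 30, 10), denoise_wassr = FALSE) {
  stopifnot(inherits(stack, "cest_stack"))
  d <- dim(stack$data)
  if (any(core > c(d[1], d[2], d[4])))
    abort("`core` ranks must not exceed the stack dimensions.")
  if (any(core < 1)) abort("`core` ranks must be >= 1.")
  out <- stack
  energy <- numeric(d[3])
  for (s in seq_len(d[3])) {
    x <- stack$data[, , s, , drop = TRUE]
    dim(x) <- c(d[1], d[2], d[4])
    # unitary 2-D DFT per offset image ("k-space")
    k <- apply(x, 3, function(im) fft(im) / sqrt(length(im)))
    dim(k) <- c(d[1], d[2], d[4])
    kt <- hosvd_truncate(k, core)
    energy[s] <- sum(Mod(kt)^2) / sum(Mod(k)^2)
    xr <- apply(kt, 3, function(im) Re(fft(im, inverse = TRUE) / sqrt(length(im))))
    dim(xr) <- c(d[1], d[2], d[4])
    out$data[, , s, ] <- xr
  }
  if (denoise_wassr && !is.null(stack$wassr)) {
    dw <- dim(stack$wassr)
    corew <- pmin(core, c(dw[1], dw[2], dw[4]))
    for (s in seq_len(dw[3])) {
      x <- stack$wassr[, , s, , drop = TRUE]
      dim(x) <- c(dw[1], dw[2], dw[4])
      k <- apply(x, 3, function(im) fft(im) / sqrt(length(im)))
      dim(k) <- c(dw[1], dw[2], dw[4])
      kt <- hosvd_truncate(k, corew)
      xr <- apply(kt, 3, function(im) Re(fft(im, inverse = TRUE) / sqrt(length(im))))
      dim(xr) <- c(dw[1], dw[2], dw[4])
      out$wassr[, , s, ] <- xr
    }
  }
  attr(out, "energy") <- energy
  out
}

#' Parametric map
#'
#' A fitted 3-D quantity (e.g. glutamate concentration in mM) with matching
#' uncertainty and fit-quality maps; voxels outside the fitted mask are NA.
#'
#' @param values,ci,r2 3-D arrays.
#' @param label Quantity name.
#' @return A list of class `parametric_map`.
#' @export
parametric_map <- function(values, ci = NULL, r2 = NULL, label = "Glu_mM") {
  structure(list(values = values, ci = ci, r2 = r2, label = label),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<parametric_map> %s: %d fitted voxels, mean %.3g, range [%.3g, %.3g]\n",
              x$label, length(v), mean(v), min(v), max(v)))
  invisible(x)
}

#' Pixel-wise glutamate quantification of a CEST stack
#'
#' Fits every voxel inside the brain mask: the voxel spectrum is normalized
#' by its M0, re-centered using the WASSR stack (when present), corrected
#' for the Rician floor, and fitted with the glutamate exchange rate fixed
#' (see [quantify_glu()]). Voxels inside the `corpus_callosum` mask use the
#' white-matter model and water concentration; all others use the
#' gray-matter model. Per-voxel failures are recorded in a failure mask and
#' never abort the map.
#'
#' @param stack A [cest_stack()] with a `brain` mask.
#' @param kex_fixed_hz Calibrated glutamate exchange rate (Hz).
#' @param models_by_tissue Named list mapping mask labels to a list with
#'   `system`, `specs` (optional), `h2o_mM` and `region`; the `default`
#'   entry covers brain voxels outside every other listed mask.
#' @param scheme Acquisition [sat_scheme()] (its offsets are replaced by the
#'   stack's).
#' @param ... Passed to [fit_zspectrum()] via [quantify_glu()].
#' @return A named list of [parametric_map()]s: `glu` (with `ci` and `r2`
#'   filled), plus a logical `failed` array attribute on `glu`.
#' @export
fit_pixelwise <- function(stack, kex_fixed_hz = 1301,
                          models_by_tissue = NULL, scheme = sat_scheme(),
                          ...) {
  stopifnot(inherits(stack, "cest_stack"))
  if (!"brain" %in% names(stack$masks)) abort("a `brain` mask is required.")
  if (is.null(models_by_tissue)) {
    models_by_tissue <- list(
      default = list(system = striatum_system(), h2o_mM = 46100,
                     region = "striatum"),
      corpus_callosum = list(system = corpus_callosum_system(),
                             h2o_mM = 40000, region = "corpus_callosum")
    )
  }
  d <- dim(stack$data)
  sp <- d[1:3]
  glu <- array(NA_real_, sp); ci <- array(NA_real_, sp)
  r2 <- array(NA_real_, sp); failed <- array(FALSE, sp)
  scheme <- update_scheme(scheme, offsets_ppm = stack$offsets_ppm)
  idx <- which(stack$masks$brain, arr.ind = TRUE)
  for (row in seq_len(nrow(idx))) {
    i <- idx[row, 1]; j <- idx[row, 2]; s <- idx[row, 3]
    tissue <- "default"
    for (nm in setdiff(names(models_by_tissue), "default"))
      if (!is.null(stack$masks[[nm]]) && stack$masks[[nm]][i, j, s])
        tissue <- nm
    mod <- models_by_tissue[[tissue]]
    res <- tryCatch({
      m0 <- stack$m0[i, j, s]
      if (!is.finite(m0) || m0 <= 0) abort("non-positive M0")
      zs <- zspectrum(stack$offsets_ppm, stack$data[i, j, s, ] / m0)
      shift <- 0
      if (!is.null(stack$wassr)) {
        ws <- zspectrum(stack$wassr_offsets_ppm,
                        stack$wassr[i, j, s, ] / m0)
        sh <- suppressWarnings(wassr_b0_shift(ws))
        if (sh$reliable) shift <- sh$shift_ppm
      }
      zs <- rician_floor_correct(zs)
      quantify_glu(zs, kex_fixed_hz = kex_fixed_hz, h2o_mM = mod$h2o_mM,
                   system = mod$system, scheme = scheme, specs = mod$specs,
                   region = mod$region %||% "striatum",
                   b0_shift_ppm = shift, floor_window_ppm = 0.2, ...)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed[i, j, s] <- TRUE
    } else {
      glu[i, j, s] <- res$glu_mM
      ci[i, j, s] <- res$ci95_mM
      r2[i, j, s] <- res$r2
    }
  }
  map <- parametric_map(glu, ci, r2, label = "Glu_mM")
  attr(map, "failed") <- failed
  list(glu = map)
}

#' Region statistics of a parametric map
#'
#' Mean, SD and the mean/SD ratio (an SNR-like quality metric for
#' quantitative maps) over the finite voxels of each named region.
#'
#' @param map A [parametric_map()].
#' @param rois Named list of 3-D logical masks.
#' @return A tibble with one row per ROI.
#' @export
region_stats <- function(map, rois) {
  stopifnot(inherits(map, "parametric_map"))
  if (length(rois) == 0) abort("`rois` must name at least one region.")
  rows <- purrr::imap(rois, function(mask, nm) {
    v <- map$values[mask]
    v <- v[is.finite(v)]
    if (length(v) == 0)
      abort(sprintf("ROI '%s' does not intersect the fitted map.", nm))
    s <- if (length(v) > 1) sd(v) else 0
    tibble(roi = nm, n_voxels = length(v), mean = mean(v), sd = s,
           mean_over_sd = if (s > 0) mean(v) / s else NA_real_)
  })
  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# NIfTI + JSON serialization
# ---------------------------------------------------------------------------

#' Read and write CEST stacks as NIfTI volumes
#'
#' A stack is serialized as `<prefix>_data.nii`, `<prefix>_m0.nii`, optional
#' `<prefix>_wassr.nii`, one `<prefix>_mask_<name>.nii` per mask, and a JSON
#' sidecar `<prefix>.json` holding the offset axes and voxel size.
#'
#' @param stack A [cest_stack()].
#' @param prefix Path prefix for the output files.
#' @return `write_cest_stack()` returns the prefix invisibly;
#'   `read_cest_stack()` returns the stack.
#' @export
write_cest_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "cest_stack"))
  RNifti::writeNifti(RNifti::asNifti(stack$data), paste0(prefix, "_data.nii"))
  RNifti::writeNifti(RNifti::asNifti(stack$m0), paste0(prefix, "_m0.nii"))
  if (!is.null(stack$wassr))
    RNifti::writeNifti(RNifti::asNifti(stack$wassr), paste0(prefix, "_wassr.nii"))
  for (nm in names(stack$masks))
    RNifti::writeNifti(RNifti::asNifti(stack$masks[[nm]] * 1L),
                       paste0(prefix, "_mask_", nm, ".nii"))
  jsonlite::write_json(
    list(offsets_ppm = stack$offsets_ppm,
         wassr_offsets_ppm = stack$wassr_offsets_ppm,
         masks = names(stack$masks), voxel_mm = stack$voxel_mm),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(prefix)
}

#' @rdname write_cest_stack
#' @export
read_cest_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  arr <- function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim = dim(v))
  }
  n_off <- length(meta$offsets_ppm)
  data <- arr(paste0(prefix, "_data.nii"))
  # NIfTI drops trailing singleton dimensions; restore them from the axes
  sp <- utils::head(c(dim(data)[seq_len(length(dim(data)) - 1L)],
                      1L, 1L), 3L)
  dim(data) <- c(sp, n_off)
  reshape3 <- function(x) { dim(x) <- sp; x }
  wassr_path <- paste0(prefix, "_wassr.nii")
  masks <- list()
  for (nm in meta$masks %||% character())
    masks[[nm]] <- reshape3(arr(paste0(prefix, "_mask_", nm, ".nii"))) > 0.5
  wassr <- NULL
  if (file.exists(wassr_path)) {
    wassr <- arr(wassr_path)
    dim(wassr) <- c(sp, length(meta$wassr_offsets_ppm))
  }
  cest_stack(
    data = data,
    m0 = reshape3(arr(paste0(prefix, "_m0.nii"))),
    offsets_ppm = meta$offsets_ppm,
    masks = masks,
    wassr = wassr,
    wassr_offsets_ppm = meta$wassr_offsets_ppm,
    voxel_mm = meta$voxel_mm %||% 0.15
  )
}
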