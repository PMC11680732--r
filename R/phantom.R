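#' Synthetic brain-like CEST phantom
#'
#' Builds a small two-slice digital phantom emulating an imaging session:
#' a gray-matter background disc (striatum-like model), a white-matter band
#' (corpus-callosum model) and a ventricle compartment (water/CSF, no
#' metabolites), with per-region or per-voxel glutamate truth. All offsets of
#' the acquisition scheme plus the M0 reference and the low-power WASSR sweep
#' are simulated, and seeded Rician noise is added to every volume.
#'
#' Identical voxels share one simulation, so uniform regions cost one
#' Z-spectrum each; a glutamate gradient costs one simulation per distinct
#' concentration.
#'
#' @param nx,ny,nslice Grid size.
#' @param glu_gm_mM Glutamate truth in gray matter: a single value or a
#'   length-2 range swept linearly left-to-right across the brain (a
#'   concentration gradient).
#' @param glu_wm_mM Glutamate truth in the white-matter band (mM).
#' @param sigma Rician noise SD as a fraction of M0.
#' @param seed RNG seed.
#' @param db0_ppm Static-field offset applied to the whole phantom (ppm).
#' @param scheme Acquisition [sat_scheme()].
#' @param with_wassr Simulate the WASSR companion stack.
#' @return A list with `stack` (a [cest_stack()] with `brain`,
#'   `corpus_callosum` and `ventricle` masks) and `truth` (a
#'   [parametric_map()] of the generating glutamate concentration).
#' @export
make_phantom <- function(nx = 12, ny = 12, nslice = 2, glu_gm_mM = 10,
                         glu_wm_mM = 5.7, sigma = 0, seed = 1,
                         db0_ppm = 0, scheme = sat_scheme(),
                         with_wassr = TRUE) {
  set.seed(seed)
  sp <- c(nx, ny, nslice)
  brain <- array(FALSE, sp); cc <- array(FALSE, sp); vent <- array(FALSE, sp)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rad <- 0.45 * min(nx, ny)
  for (i in 1:nx) for (j in 1:ny) {
    if ((i - cx)^2 + (j - cy)^2 <= rad^2) brain[i, j, ] <- TRUE
  }
  ccrow <- max(2L, round(ny * 0.7))
  cc[, ccrow, ] <- brain[, ccrow, ]
  vr <- max(1L, round(rad * 0.3))
  for (i in 1:nx) for (j in 1:ny) {
    if ((i - cx)^2 + (j - cy)^2 <= vr^2) vent[i, j, ] <- TRUE
  }
  cc[vent] <- FALSE

  glu_field <- array(NA_real_, sp)
  grad <- length(glu_gm_mM) == 2
  for (i in 1:nx) {
    g <- if (grad)
      glu_gm_mM[1] + (glu_gm_mM[2] - glu_gm_mM[1]) * (i - 1) / max(nx - 1, 1)
    else glu_gm_mM[1]
    glu_field[i, , ] <- g
  }
  glu_field[cc] <- glu_wm_mM
  glu_field[vent] <- 0
  glu_field[!brain] <- NA_real_

  shifted <- update_scheme(scheme, offsets_ppm = scheme$offsets_ppm - db0_ppm)
  m0_scheme <- update_scheme(shifted, offsets_ppm = scheme$m0_offset_ppm)
  wsc <- wassr_scheme(scheme)
  wshift <- update_scheme(wsc, offsets_ppm = wsc$offsets_ppm - db0_ppm)

  # simulate unnormalized Mz so the stack carries a real M0 volume
  sim_mz <- function(system, sch) {
    bm_mz_cpp(sch$offsets_ppm, pools_matrix(system), sch$b1_ut, sch$n_pulses,
              sch$pulse_s, sch$delay_s, sch$recovery_s, sch$larmor_mhz, 0L, 1)
  }
  tissue_key <- function(i, j, s) {
    if (!brain[i, j, s]) return(NA_character_)
    if (vent[i, j, s]) return("vent")
    if (cc[i, j, s]) return(sprintf("cc:%.6g", glu_field[i, j, s]))
    sprintf("gm:%.6g", glu_field[i, j, s])
  }
  sys_for <- function(key) {
    if (key == "vent") {
      pool_system(pool("water", 0, 0, 1, 4.0, 110e-3), region = "ventricle")
    } else {
      g <- as.numeric(sub("^..:", "", key))
      if (startsWith(key, "cc")) corpus_callosum_system(glu_mM = g)
      else striatum_system(glu_mM = g)
    }
  }
  cache <- new.env(parent = emptyenv())
  sim_for <- function(key) {
    if (!is.null(cache[[key]])) return(cache[[key]])
    sys <- sys_for(key)
    val <- list(
      z = sim_mz(sys, shifted),
      m0 = sim_mz(sys, m0_scheme),
      w = if (with_wassr) sim_mz(sys, wshift) else NULL
    )
    cache[[key]] <- val
    val
  }

  nf <- length(scheme$offsets_ppm)
  data <- array(0, c(sp, nf))
  m0 <- array(0, sp)
  wassr <- if (with_wassr) array(0, c(sp, length(wsc$offsets_ppm))) else NULL
  for (s in 1:nslice) for (j in 1:ny) for (i in 1:nx) {
    key <- tissue_key(i, j, s)
    if (is.na(key)) next
    sim <- sim_for(key)
    data[i, j, s, ] <- sim$z
    m0[i, j, s] <- sim$m0
    if (with_wassr) wassr[i, j, s, ] <- sim$w
  }
  if (sigma > 0) {
    ric <- function(x) sqrt((x + rnorm(length(x), 0, sigma))^2 +
                              rnorm(length(x), 0, sigma)^2)
    data[] <- ric(data)
    m0[] <- ric(m0)
    if (with_wassr) wassr[] <- ric(wassr)
  }
  stack <- cest_stack(
    data = data, m0 = m0, offsets_ppm = scheme$offsets_ppm,
    masks = list(brain = brain, corpus_callosum = cc, ventricle = vent),
    wassr = wassr,
    wassr_offsets_ppm = if (with_wassr) wsc$offsets_ppm else NULL
  )
  list(stack = stack, truth = parametric_map(glu_field, label = "Glu_mM"))
}
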