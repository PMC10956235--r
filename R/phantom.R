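#' Structure set
#'
#' Named binary masks on a shared voxel grid, together with per-target
#' prescription doses. The five planning target volumes are always named
#' `PTV-GTV`, `PTV-1`, `PTV-2`, `PTV-LN(L)` and `PTV-LN(R)`; the organ-at-risk
#' roster is [oar_roster()].
#'
#' @param masks named list of logical 3D arrays, all of the same dimension.
#' @param prescriptions named numeric vector of prescription doses in Gy,
#'   one entry per PTV.
#' @param fractions integer number of treatment fractions (bookkeeping only;
#'   all doses in the package are total physical dose in Gy).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, prescriptions, fractions = 33L) {
  if (!length(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a non-empty named list")
  sh <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), sh))
      stop(sprintf("mask '%s' is not a logical array on the shared grid", nm))
  }
  if (is.null(names(prescriptions)))
    stop("`prescriptions` must be named by PTV")
  missing_ptv <- setdiff(names(prescriptions), names(masks))
  if (length(missing_ptv))
    stop("prescription for absent structure: ", paste(missing_ptv, collapse = ", "))
  structure(
    list(masks = masks, prescriptions = prescriptions,
         fractions = as.integer(fractions)),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures, %d targets\n",
              length(x$masks), length(x$prescriptions)))
  invisible(x)
}

#' The five planning-target-volume names
#' @return character vector of the fixed PTV names.
#' @export
ptv_names <- function() {
  c("PTV-GTV", "PTV-1", "PTV-2", "PTV-LN(L)", "PTV-LN(R)")
}

#' The seventeen organ-at-risk names, in fixed roster order
#'
#' The order is the one used for the OAR channels of [encode_inputs()].
#'
#' @return character vector of 17 structure names.
#' @export
oar_roster <- function() {
  c("Body", "Brainstem", "Spinal cord", "Chiasm", "Tongue",
    "Left optic nerve", "Right optic nerve", "Left lens", "Right lens",
    "Left temporal lobe", "Right temporal lobe",
    "Left mandible", "Right mandible",
    "Left temporomandibular joint", "Right temporomandibular joint",
    "Left parotid gland", "Right parotid gland")
}

.ellipsoid_mask <- function(ctr_xyz, center, semi) {
  dx <- (ctr_xyz[, 1] - center[1]) / semi[1]
  dy <- (ctr_xyz[, 2] - center[2]) / semi[2]
  dz <- (ctr_xyz[, 3] - center[3]) / semi[3]
  dx * dx + dy * dy + dz * dz <= 1
}

.cylinder_z_mask <- function(ctr_xyz, center_xy, radius, zmin, zmax) {
  dx <- ctr_xyz[, 1] - center_xy[1]
  dy <- ctr_xyz[, 2] - center_xy[2]
  dx * dx + dy * dy <= radius^2 & ctr_xyz[, 3] >= zmin & ctr_xyz[, 3] <= zmax
}

#' Generate a synthetic nasopharyngeal-carcinoma planning case
#'
#' Builds a seeded head-and-neck phantom: a water-equivalent elliptic-cylinder
#' body, three concentric nested primary targets (`PTV-GTV` inside `PTV-1`
#' inside `PTV-2`), two lateral nodal targets, and the full 17-organ roster
#' (midline brainstem and spinal cord posterior to the targets, lateral
#' parotids overlapping the `PTV-2` edge, paired lenses/optic nerves/chiasm
#' and the remaining head-and-neck organs). All shapes are parametric
#' ellipsoids and cylinders with a small seeded jitter of position and size,
#' so different seeds give different but anatomically equivalent cases.
#' Structures are defined in fixed millimetre coordinates about the
#' isocenter, making the phantom resolution-agnostic.
#'
#' @param seed integer seed; the phantom is a deterministic function of it.
#' @param shape integer length-3 voxel counts, default `c(64, 64, 48)`.
#' @param spacing numeric length-3 spacing in mm, default 4 mm isotropic.
#' @param prescriptions named numeric vector of PTV prescriptions in Gy.
#'   Defaults to 70 / 60 / 54 / 66 / 66 Gy for
#'   PTV-GTV / PTV-1 / PTV-2 / PTV-LN(L) / PTV-LN(R).
#' @return list with elements `vol` (a [volume_grid()]) and `ss`
#'   (a [structure_set()]).
#' @examples
#' case <- generate_phantom(seed = 1, shape = c(32, 32, 24), spacing = c(8, 8, 8))
#' case$ss
#' @export
generate_phantom <- function(seed, shape = c(64L, 64L, 48L),
                             spacing = c(4, 4, 4),
                             prescriptions = c(
                               "PTV-GTV" = 70, "PTV-1" = 60, "PTV-2" = 54,
                               "PTV-LN(L)" = 66, "PTV-LN(R)" = 66)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("invalid `shape`")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid `spacing`")
  half <- shape * spacing / 2
  # the anatomy spans fixed mm extents about the isocenter
  need <- c(108, 95, 92)
  if (any(half < need))
    stop(sprintf(
      "grid too small to place all structures: half-extents (%.0f, %.0f, %.0f) mm, need >= (%d, %d, %d) mm",
      half[1], half[2], half[3], need[1], need[2], need[3]))
  if (!setequal(names(prescriptions), ptv_names()))
    stop("`prescriptions` must name exactly the five PTVs")
  prescriptions <- prescriptions[ptv_names()]

  with_private_seed(seed, {
    jit <- function(n = 3, d = 2) stats::runif(n, -d, d)
    jsc <- function() stats::runif(1, 0.96, 1.06)

    vol0 <- volume_grid(array(0, shape), spacing)
    ctr <- voxel_centers(vol0)

    body_semi <- c(105, 92) * jsc()
    body <- (ctr[, 1] / body_semi[1])^2 + (ctr[, 2] / body_semi[2])^2 <= 1

    density <- array(0, shape)
    density[body] <- 1.0
    vol <- volume_grid(density, spacing)

    masks <- list()
    # concentric primary targets: shared jittered centre, increasing semi-axes
    tc <- jit(3, 2)
    s_gtv <- c(26, 21, 19) * jsc()
    s_p1 <- s_gtv + c(9, 9, 9) * jsc()
    s_p2 <- s_p1 + c(18, 14, 13) * jsc()
    masks[["PTV-GTV"]] <- .ellipsoid_mask(ctr, tc, s_gtv)
    masks[["PTV-1"]] <- .ellipsoid_mask(ctr, tc, s_p1)
    masks[["PTV-2"]] <- .ellipsoid_mask(ctr, tc, s_p2)
    masks[["PTV-LN(L)"]] <- .ellipsoid_mask(ctr, c(62, 8, -34) + jit(), c(14, 14, 24) * jsc())
    masks[["PTV-LN(R)"]] <- .ellipsoid_mask(ctr, c(-62, 8, -34) + jit(), c(14, 14, 24) * jsc())

    masks[["Body"]] <- body
    masks[["Brainstem"]] <- .cylinder_z_mask(ctr, c(0, 52) + jit(2, 2), 10 * jsc(),
                                             -15, min(75, half[3] - spacing[3]))
    masks[["Spinal cord"]] <- .cylinder_z_mask(ctr, c(0, 58) + jit(2, 2), 5.5 * jsc(),
                                               max(-94, -half[3] + spacing[3]), -15)
    masks[["Chiasm"]] <- .ellipsoid_mask(ctr, c(0, -25, 36) + jit(3, 1), c(12, 6, 5) * jsc())
    masks[["Tongue"]] <- .ellipsoid_mask(ctr, c(0, -52, -36) + jit(), c(24, 24, 19) * jsc())
    masks[["Left optic nerve"]] <- .ellipsoid_mask(ctr, c(16, -45, 36) + jit(3, 1), c(4, 14, 4) * jsc())
    masks[["Right optic nerve"]] <- .ellipsoid_mask(ctr, c(-16, -45, 36) + jit(3, 1), c(4, 14, 4) * jsc())
    masks[["Left lens"]] <- .ellipsoid_mask(ctr, c(27, -78, 34) + jit(3, 1), rep(4.5 * jsc(), 3))
    masks[["Right lens"]] <- .ellipsoid_mask(ctr, c(-27, -78, 34) + jit(3, 1), rep(4.5 * jsc(), 3))
    masks[["Left temporal lobe"]] <- .ellipsoid_mask(ctr, c(58, -5, 44) + jit(), c(24, 28, 22) * jsc())
    masks[["Right temporal lobe"]] <- .ellipsoid_mask(ctr, c(-58, -5, 44) + jit(), c(24, 28, 22) * jsc())
    masks[["Left mandible"]] <- .ellipsoid_mask(ctr, c(42, -48, -46) + jit(), c(14, 26, 23) * jsc())
    masks[["Right mandible"]] <- .ellipsoid_mask(ctr, c(-42, -48, -46) + jit(), c(14, 26, 23) * jsc())
    masks[["Left temporomandibular joint"]] <- .ellipsoid_mask(ctr, c(58, 2, 2) + jit(3, 1), rep(8.5 * jsc(), 3))
    masks[["Right temporomandibular joint"]] <- .ellipsoid_mask(ctr, c(-58, 2, 2) + jit(3, 1), rep(8.5 * jsc(), 3))
    masks[["Left parotid gland"]] <- .ellipsoid_mask(ctr, c(60, 12, -10) + jit(), c(13, 19, 24) * jsc())
    masks[["Right parotid gland"]] <- .ellipsoid_mask(ctr, c(-60, 12, -10) + jit(), c(13, 19, 24) * jsc())

    masks <- lapply(masks, function(m) array(m & body, shape))

    list(vol = vol,
         ss = structure_set(masks, prescriptions))
  })
}

#' Encode a planning case as prediction-model input channels
#'
#' Produces the target channel (each voxel carries the maximum prescription
#' dose among the PTVs containing it, zero outside all PTVs) and the ordered
#' list of binary OAR channels.
#'
#' @param vol a [volume_grid()].
#' @param ss a [structure_set()] containing the five PTVs and the OAR roster.
#' @return list with `ptv_channel` (3D numeric array, Gy) and `oar_channels`
#'   (named list of logical arrays in [oar_roster()] order).
#' @export
encode_inputs <- function(vol, ss) {
  missing_ptv <- setdiff(ptv_names(), names(ss$masks))
  if (length(missing_ptv))
    stop("missing PTV structure: ", paste(missing_ptv, collapse = ", "))
  ch <- array(0, vol$shape)
  for (nm in ptv_names()) {
    px <- ss$prescriptions[[nm]]
    m <- ss$masks[[nm]]
    ch[m] <- pmax(ch[m], px)
  }
  oars <- intersect(oar_roster(), names(ss$masks))
  list(ptv_channel = ch, oar_channels = ss$masks[oars])
}

#' Surrogate fluence prediction
#'
#' Stands in for a trained fluence-prediction network: for each beam, each
#' beamlet receives the maximum encoded prescription value found along its
#' ray through the target channel, scaled by `1 / n_beams` so that the
#' nine-beam sum of calibrated beamlet doses lands near the prescription,
#' then perturbed by multiplicative lognormal noise of parameter `noise_sd`
#' (mean-one; `noise_sd = 0` is noiseless and seed-independent). Rays missing
#' every PTV give zero fluence.
#'
#' @param vol a [volume_grid()].
#' @param ss a [structure_set()].
#' @param beams a [beam_setup()].
#' @param noise_sd lognormal sdlog of the multiplicative prediction error
#'   (>= 0), default 0.05.
#' @param seed integer seed for the noise stream.
#' @return list of [fluence_map()] objects, one per beam.
#' @export
surrogate_predict_fluence <- function(vol, ss, beams, noise_sd = 0.05, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  enc <- encode_inputs(vol, ss)
  nb <- length(beams$gantry_angles)
  step <- min(vol$spacing) / 2
  extent <- sqrt(sum((vol$shape * vol$spacing)[1:2]^2))
  ts <- seq(-extent / 2, extent / 2, by = step)

  maps <- vector("list", nb)
  for (b in seq_len(nb)) {
    geo <- beam_geometry(beams, b)
    bl <- beamlet_centers(beams)  # (u, v) centres, column-major over values
    n_bl <- nrow(bl)
    vmax <- numeric(n_bl)
    # march all beamlet rays in lock-step through the target channel
    for (t in ts) {
      pts <- cbind(
        geo$u_axis[1] * bl[, 1] + geo$dir[1] * t,
        geo$u_axis[2] * bl[, 1] + geo$dir[2] * t,
        bl[, 2]
      )
      vmax <- pmax(vmax, sample_field(vol, pts, field = enc$ptv_channel))
    }
    vals <- matrix(vmax / nb, beams$fluence_shape[1], beams$fluence_shape[2])
    maps[[b]] <- fluence_map(b, vals, beams$fluence_spacing,
                             gantry_angle = beams$gantry_angles[b])
  }
  if (noise_sd > 0) {
    maps <- with_private_seed(seed, {
      lapply(maps, function(fm) {
        noise <- matrix(
          stats::rlnorm(length(fm$values), meanlog = -noise_sd^2 / 2, sdlog = noise_sd),
          nrow(fm$values), ncol(fm$values))
        fm$values <- pmax(fm$values * noise, 0)
        fm
      })
    })
  }
  maps
}
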