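#' Beam arrangement
#'
#' Nine equally spaced coplanar 6 MV beams are the default arrangement
#' (gantry angles 0, 40, ..., 320 degrees). Gantry 0 enters anteriorly and
#' travels in +y; beamlets are parallel (no divergence) and are laid out on a
#' rectangular fluence grid in the isocenter plane, with axis u
#' (in-plane, perpendicular to the beam) and axis v parallel to z.
#'
#' @param gantry_angles numeric vector of gantry angles in degrees.
#' @param isocenter numeric length-3 isocenter position in mm.
#' @param source_axis_distance source-axis distance in mm (carried for
#'   completeness; beamlets are parallel).
#' @param fluence_spacing beamlet spacing `c(u, v)` in mm at the isocenter
#'   plane. Default 10 mm (desk scale); the native 2.5 mm grid is supported
#'   by the same code path.
#' @param fluence_shape integer beamlet counts `c(nu, nv)`, default 20 x 20.
#' @return An object of class `beam_setup`.
#' @export
beam_setup <- function(gantry_angles = seq(0, 320, by = 40),
                       isocenter = c(0, 0, 0),
                       source_axis_distance = 1000,
                       fluence_spacing = c(10, 10),
                       fluence_shape = c(20L, 20L)) {
  if (any(fluence_spacing <= 0)) stop("`fluence_spacing` must be > 0")
  fluence_shape <- as.integer(fluence_shape)
  if (length(fluence_shape) != 2L || any(fluence_shape < 1L))
    stop("invalid `fluence_shape`")
  structure(
    list(gantry_angles = as.numeric(gantry_angles),
         isocenter = as.numeric(isocenter),
         source_axis_distance = source_axis_distance,
         fluence_spacing = as.numeric(fluence_spacing),
         fluence_shape = fluence_shape),
    class = "beam_setup"
  )
}

#' Per-beam unit vectors
#' @keywords internal
beam_geometry <- function(beams, b) {
  th <- beams$gantry_angles[b] * pi / 180
  list(dir = c(sin(th), cos(th), 0),      # direction of travel
       u_axis = c(cos(th), -sin(th), 0))  # in-plane lateral axis
}

#' Beamlet centre coordinates (u, v) in the isocenter plane
#'
#' Ordering is column-major over the fluence `values` matrix (u index
#' fastest), matching [fluence_vector()].
#' @keywords internal
beamlet_centers <- function(beams) {
  nu <- beams$fluence_shape[1]; nv <- beams$fluence_shape[2]
  su <- beams$fluence_spacing[1]; sv <- beams$fluence_spacing[2]
  u <- (seq_len(nu) - (nu + 1) / 2) * su
  v <- (seq_len(nv) - (nv + 1) / 2) * sv
  cbind(rep(u, times = nv), rep(v, each = nu))
}

#' Fluence map for one beam
#'
#' @param beam_index integer beam number.
#' @param values nonnegative numeric matrix `nu x nv` of beamlet intensities
#'   (arbitrary units; 1.0 = open reference beamlet).
#' @param spacing beamlet spacing `c(u, v)` in mm.
#' @param gantry_angle gantry angle in degrees (metadata).
#' @return An object of class `fluence_map`.
#' @export
fluence_map <- function(beam_index, values, spacing, gantry_angle = NA_real_) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("fluence values must be finite and >= 0")
  structure(
    list(beam_index = as.integer(beam_index),
         values = values,
         spacing = as.numeric(spacing),
         origin_at_isocenter_plane = -(dim(values) - 1) / 2 * as.numeric(spacing),
         gantry_angle = as.numeric(gantry_angle)),
    class = "fluence_map"
  )
}

#' Concatenate per-beam fluence maps into the beamlet weight vector
#'
#' Beamlet ordering is beam-major, column-major within each beam's fluence
#' matrix — the ordering of [build_influence()] columns.
#'
#' @param fluences list of [fluence_map()].
#' @return numeric vector of beamlet weights.
#' @export
fluence_vector <- function(fluences) {
  unlist(lapply(fluences, function(f) as.vector(f$values)), use.names = FALSE)
}

#' Reshape a beamlet weight vector into per-beam fluence maps
#'
#' @param w numeric beamlet vector in [fluence_vector()] order.
#' @param beams a [beam_setup()].
#' @return list of [fluence_map()].
#' @export
vector_to_fluence <- function(w, beams) {
  nu <- beams$fluence_shape[1]; nv <- beams$fluence_shape[2]
  npb <- nu * nv
  nb <- length(beams$gantry_angles)
  if (length(w) != npb * nb) stop("beamlet vector length mismatch")
  lapply(seq_len(nb), function(b) {
    fluence_map(b, matrix(w[(b - 1) * npb + seq_len(npb)], nu, nv),
                beams$fluence_spacing, gantry_angle = beams$gantry_angles[b])
  })
}

#' Pencil-beam kernel parameters
#'
#' The simplified photon kernel: dose on a beamlet ray is
#' `calibration * buildup(depth) * exp(-mu_eff * depth)` with linear buildup
#' over `buildup_mm`, spread laterally by a Gaussian of `sigma_mm` integrated
#' across the beamlet aperture. Depth is radiological depth (density
#' line-integral, mm water-equivalent). The calibration constant
#' `exp(mu_eff * calib_depth_mm)` makes a unit-fluence open field deposit
#' 1 Gy at `calib_depth_mm` water depth.
#'
#' @param mu_eff effective linear attenuation in 1/mm (6 MV default 0.005).
#' @param buildup_mm linear buildup depth in mm, default 15.
#' @param sigma_mm lateral Gaussian sigma in mm, default 3.
#' @param calib_depth_mm calibration depth in mm, default 100.
#' @param truncate_rel influence entries below this fraction of their
#'   beamlet's maximum are dropped to keep the matrix sparse.
#' @param step_mm ray-marching step for radiological depth in mm; default
#'   half the smallest voxel spacing.
#' @return list of kernel parameters, class `pencil_beam_kernel`.
#' @export
pencil_beam_kernel <- function(mu_eff = 0.005, buildup_mm = 15, sigma_mm = 3,
                               calib_depth_mm = 100, truncate_rel = 1e-4,
                               step_mm = NULL) {
  structure(
    list(mu_eff = mu_eff, buildup_mm = buildup_mm, sigma_mm = sigma_mm,
         calib_depth_mm = calib_depth_mm, truncate_rel = truncate_rel,
         step_mm = step_mm),
    class = "pencil_beam_kernel"
  )
}

# radiological depth (mm water-equivalent) of each point in `ctr` along -dir
.radiological_depth <- function(vol, ctr, dir, step) {
  extent <- sqrt(sum((vol$shape * vol$spacing)[1:2]^2))
  K <- ceiling(extent / step)
  depth <- numeric(nrow(ctr))
  pts <- ctr
  for (k in seq_len(K)) {
    t <- (k - 0.5) * step
    pts[, 1] <- ctr[, 1] - dir[1] * t
    pts[, 2] <- ctr[, 2] - dir[2] * t
    depth <- depth + sample_field(vol, pts) * step
  }
  depth
}

#' Build the sparse dose-influence matrix
#'
#' Rows are body voxels (density > 0), columns are beamlets of all beams in
#' [fluence_vector()] order; entries are Gy per unit beamlet fluence under
#' the [pencil_beam_kernel()]. The build is deterministic.
#'
#' @param vol a [volume_grid()].
#' @param beams a [beam_setup()]; the isocenter must lie inside the volume.
#' @param kernel a [pencil_beam_kernel()].
#' @return An object of class `influence_matrix`: a `Matrix::dgCMatrix`
#'   `matrix`, the linear `voxel_idx` of its rows, `vol_shape`, `beams` and
#'   `kernel`.
#' @export
build_influence <- function(vol, beams, kernel = pencil_beam_kernel()) {
  iso <- beams$isocenter
  lo <- vol$origin; hi <- vol$origin + vol$shape * vol$spacing
  if (any(iso < lo) || any(iso > hi))
    stop("isocenter lies outside the volume")
  step <- if (is.null(kernel$step_mm)) min(vol$spacing) / 2 else kernel$step_mm

  voxel_idx <- which(as.vector(vol$density > 0))
  nb <- length(beams$gantry_angles)
  nu <- beams$fluence_shape[1]; nv <- beams$fluence_shape[2]
  npb <- nu * nv
  ncols <- npb * nb
  if (!length(voxel_idx)) {
    return(structure(
      list(matrix = Matrix::sparseMatrix(i = integer(), j = integer(),
                                         x = numeric(), dims = c(0L, ncols)),
           voxel_idx = integer(), vol_shape = vol$shape,
           beams = beams, kernel = kernel),
      class = "influence_matrix"))
  }

  ctr <- voxel_centers(vol, voxel_idx)
  su <- beams$fluence_spacing[1]; sv <- beams$fluence_spacing[2]
  calib <- exp(kernel$mu_eff * kernel$calib_depth_mm)
  n_off_u <- ceiling((4 * kernel$sigma_mm + su / 2) / su)
  n_off_v <- ceiling((4 * kernel$sigma_mm + sv / 2) / sv)
  off <- expand.grid(ou = -n_off_u:n_off_u, ov = -n_off_v:n_off_v)

  ii <- jj <- xx <- vector("list", nb)
  for (b in seq_len(nb)) {
    geo <- beam_geometry(beams, b)
    depth <- .radiological_depth(vol, ctr, geo$dir, step)
    dk <- calib * pmin(depth / kernel$buildup_mm, 1) * exp(-kernel$mu_eff * depth)
    p <- ctr[, 1] * geo$u_axis[1] + ctr[, 2] * geo$u_axis[2]
    q <- ctr[, 3]
    fi0 <- round(p / su + (nu + 1) / 2)
    fj0 <- round(q / sv + (nv + 1) / 2)
    act <- which(dk > 0)
    ti <- tj <- tx <- vector("list", nrow(off))
    for (o in seq_len(nrow(off))) {
      i_b <- fi0[act] + off$ou[o]
      j_b <- fj0[act] + off$ov[o]
      ok <- i_b >= 1 & i_b <= nu & j_b >= 1 & j_b <= nv
      if (!any(ok)) next
      a <- act[ok]; i_b <- i_b[ok]; j_b <- j_b[ok]
      dp <- p[a] - (i_b - (nu + 1) / 2) * su
      dq <- q[a] - (j_b - (nv + 1) / 2) * sv
      fx <- stats::pnorm((dp + su / 2) / kernel$sigma_mm) -
        stats::pnorm((dp - su / 2) / kernel$sigma_mm)
      fy <- stats::pnorm((dq + sv / 2) / kernel$sigma_mm) -
        stats::pnorm((dq - sv / 2) / kernel$sigma_mm)
      val <- dk[a] * fx * fy
      keep <- val > 0
      if (!any(keep)) next
      ti[[o]] <- a[keep]
      tj[[o]] <- (b - 1L) * npb + (j_b[keep] - 1L) * nu + i_b[keep]
      tx[[o]] <- val[keep]
    }
    bi <- unlist(ti, use.names = FALSE)
    bj <- unlist(tj, use.names = FALSE)
    bx <- unlist(tx, use.names = FALSE)
    if (length(bx)) {
      # per-beamlet relative truncation keeps columns sparse
      o <- order(bj, bx)
      last <- !duplicated(bj[o], fromLast = TRUE)
      colmax <- numeric(ncols)
      colmax[bj[o][last]] <- bx[o][last]
      keep <- bx >= kernel$truncate_rel * colmax[bj]
      bi <- bi[keep]; bj <- bj[keep]; bx <- bx[keep]
    }
    ii[[b]] <- bi; jj[[b]] <- bj; xx[[b]] <- bx
  }

  D <- Matrix::sparseMatrix(
    i = unlist(ii, use.names = FALSE),
    j = unlist(jj, use.names = FALSE),
    x = unlist(xx, use.names = FALSE),
    dims = c(length(voxel_idx), ncols))
  structure(
    list(matrix = D, voxel_idx = voxel_idx, vol_shape = vol$shape,
         beams = beams, kernel = kernel),
    class = "influence_matrix"
  )
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d voxels x %d beamlets, %d nonzeros\n",
              nrow(x$matrix), ncol(x$matrix), Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' Compute the dose distribution for a set of fluence maps
#'
#' Dose is linear in fluence: `d = D w` with `w` the concatenated beamlet
#' vector.
#'
#' @param D an [build_influence()] result.
#' @param fluences list of [fluence_map()], or a numeric beamlet vector.
#' @return 3D numeric array of dose in Gy on the planning grid (zero outside
#'   the body).
#' @export
compute_dose <- function(D, fluences) {
  w <- if (is.numeric(fluences)) fluences else fluence_vector(fluences)
  if (length(w) != ncol(D$matrix)) stop("fluence/beamlet dimension mismatch")
  if (any(w < 0)) stop("fluence must be >= 0")
  dose <- array(0, D$vol_shape)
  if (nrow(D$matrix))
    dose[D$voxel_idx] <- as.numeric(D$matrix %*% w)
  dose
}
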