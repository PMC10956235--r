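#' Planning volume grid
#'
#' A regular voxel grid holding per-voxel relative electron density
#' (dimensionless, water = 1.0). Coordinates are in millimetres; voxel
#' `(i, j, k)` has its centre at `origin + (c(i, j, k) - 0.5) * spacing`.
#' Axes are fixed patient axes: x = patient left, y = posterior,
#' z = superior.
#'
#' @param density 3D numeric array of relative electron densities (>= 0).
#' @param spacing numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin numeric length-3, position in mm of the corner of voxel
#'   `(1, 1, 1)`. Default centres the volume on the origin, which is also
#'   the beam isocenter used throughout.
#' @return An object of class `volume_grid` with fields `shape`, `spacing`,
#'   `origin` and `density`.
#' @export
volume_grid <- function(density, spacing, origin = NULL) {
  if (!is.array(density) || length(dim(density)) != 3L)
    stop("`density` must be a 3D array")
  if (any(density < 0)) stop("density must be >= 0 everywhere")
  shape <- dim(density)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (is.null(origin)) origin <- -shape * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(
    list(shape = shape, spacing = spacing, origin = origin, density = density),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' Voxel centre coordinates
#'
#' @param vol a [volume_grid()].
#' @param idx optional integer vector of linear voxel indices; default all.
#' @return n x 3 matrix of voxel-centre coordinates in mm.
#' @keywords internal
voxel_centers <- function(vol, idx = NULL) {
  sh <- vol$shape
  if (is.null(idx)) idx <- seq_len(prod(sh))
  idx0 <- idx - 1L
  i <- idx0 %% sh[1]
  j <- (idx0 %/% sh[1]) %% sh[2]
  k <- idx0 %/% (sh[1] * sh[2])
  cbind(
    vol$origin[1] + (i + 0.5) * vol$spacing[1],
    vol$origin[2] + (j + 0.5) * vol$spacing[2],
    vol$origin[3] + (k + 0.5) * vol$spacing[3]
  )
}

#' Nearest-voxel lookup of a per-voxel field at arbitrary points
#'
#' Points outside the volume return `outside`.
#'
#' @param vol a [volume_grid()].
#' @param field 3D array on the grid (defaults to the density).
#' @param pts n x 3 matrix of mm coordinates.
#' @param outside value returned for points outside the grid.
#' @return numeric vector of length n.
#' @keywords internal
sample_field <- function(vol, pts, field = vol$density, outside = 0) {
  sh <- vol$shape
  i <- floor((pts[, 1] - vol$origin[1]) / vol$spacing[1]) + 1
  j <- floor((pts[, 2] - vol$origin[2]) / vol$spacing[2]) + 1
  k <- floor((pts[, 3] - vol$origin[3]) / vol$spacing[3]) + 1
  ok <- i >= 1 & i <= sh[1] & j >= 1 & j <= sh[2] & k >= 1 & k <= sh[3]
  out <- rep(outside, nrow(pts))
  if (any(ok)) {
    lin <- (i[ok] - 1) + (j[ok] - 1) * sh[1] + (k[ok] - 1) * sh[1] * sh[2] + 1
    out[ok] <- field[lin]
  }
  out
}

# Evaluate an expression with a private, seeded RNG stream, restoring the
# caller's RNG state afterwards.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
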