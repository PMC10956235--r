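#' Isotropic Euclidean expansion of a binary mask
#'
#' A voxel is included in the expansion iff its centre lies within
#' `distance_mm` (Euclidean, spacing-aware, ties at exactly `distance_mm`
#' included) of the centre of any source voxel. `distance_mm = 0` returns the
#' mask unchanged. This is the margin semantics used for the planning
#' organ-at-risk volumes ("Brainstem 3 mm", "Spinal cord 3 mm") and for all
#' auxiliary-structure constructions.
#'
#' @param mask logical 3D array.
#' @param distance_mm expansion margin in mm (>= 0; contraction is out of
#'   scope).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return logical 3D array of the same shape.
#' @export
expand_mask <- function(mask, distance_mm, spacing) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3D array")
  if (distance_mm < 0) stop("`distance_mm` must be >= 0")
  if (distance_mm == 0 || !any(mask)) return(mask)
  spacing <- as.numeric(spacing)
  sh <- dim(mask)
  r <- floor(distance_mm / spacing)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (offs$dx * spacing[1])^2 + (offs$dy * spacing[2])^2 + (offs$dz * spacing[3])^2
  offs <- offs[d2 <= distance_mm^2, , drop = FALSE]
  out <- array(FALSE, sh)
  for (o in seq_len(nrow(offs))) {
    dx <- offs$dx[o]; dy <- offs$dy[o]; dz <- offs$dz[o]
    xs <- max(1, 1 + dx):min(sh[1], sh[1] + dx)
    ys <- max(1, 1 + dy):min(sh[2], sh[2] + dy)
    zs <- max(1, 1 + dz):min(sh[3], sh[3] + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] | mask[xs - dx, ys - dy, zs - dz]
  }
  out
}

#' Boolean difference of two masks
#'
#' @param a,b logical 3D arrays on the same grid.
#' @return `a & !b`.
#' @export
subtract_mask <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a & !b
}

#' Add the auxiliary optimization structures to a structure set
#'
#' Constructs, from the base targets and the reference (predicted-fluence
#' plan) dose:
#' \itemize{
#'   \item `PTV-1-Crop`: PTV-1 minus the 3 mm expansion of PTV-GTV;
#'   \item `PTV-2-Crop`: PTV-2 minus the 3 mm expansion of the union of
#'     PTV-1, PTV-LN(L) and PTV-LN(R);
#'   \item `Ring 2 cm`: the 2 cm-wide shell between PTV-2 expanded by 2 mm
#'     and PTV-2 expanded by 22 mm;
#'   \item `40 Gy-PTV2`: voxels with reference dose >= 40 Gy, minus the 3 mm
#'     expansion of PTV-2;
#'   \item `Brainstem 3 mm` / `Spinal cord 3 mm`: 3 mm planning
#'     organ-at-risk expansions;
#'   \item `Left/Right normal parotid`: parotid minus the union of all PTVs.
#' }
#' All auxiliary structures are intersected with the body.
#'
#' @param ss a [structure_set()].
#' @param reference_dose 3D dose array in Gy (the predicted-fluence plan
#'   dose).
#' @param vol the [volume_grid()] the masks live on.
#' @return the augmented [structure_set()].
#' @export
make_auxiliary_structures <- function(ss, reference_dose, vol) {
  need <- c(ptv_names(), "Body", "Brainstem", "Spinal cord",
            "Left parotid gland", "Right parotid gland")
  missing <- setdiff(need, names(ss$masks))
  if (length(missing))
    stop("missing base structure: ", paste(missing, collapse = ", "))
  if (!identical(dim(reference_dose), vol$shape))
    stop("reference dose is not on the planning grid")
  sp <- vol$spacing
  m <- ss$masks
  body <- m[["Body"]]
  ptv_union <- m[["PTV-GTV"]] | m[["PTV-1"]] | m[["PTV-2"]] |
    m[["PTV-LN(L)"]] | m[["PTV-LN(R)"]]

  aux <- list(
    "PTV-1-Crop" = subtract_mask(m[["PTV-1"]], expand_mask(m[["PTV-GTV"]], 3, sp)),
    "PTV-2-Crop" = subtract_mask(
      m[["PTV-2"]],
      expand_mask(m[["PTV-1"]] | m[["PTV-LN(L)"]] | m[["PTV-LN(R)"]], 3, sp)),
    "Ring 2 cm" = subtract_mask(expand_mask(m[["PTV-2"]], 22, sp),
                                expand_mask(m[["PTV-2"]], 2, sp)),
    "40 Gy-PTV2" = subtract_mask(reference_dose >= 40,
                                 expand_mask(m[["PTV-2"]], 3, sp)),
    "Brainstem 3 mm" = expand_mask(m[["Brainstem"]], 3, sp),
    "Spinal cord 3 mm" = expand_mask(m[["Spinal cord"]], 3, sp),
    "Left normal parotid" = subtract_mask(m[["Left parotid gland"]], ptv_union),
    "Right normal parotid" = subtract_mask(m[["Right parotid gland"]], ptv_union)
  )
  aux <- lapply(aux, function(x) x & body)
  out <- ss
  out$masks[names(aux)] <- aux
  out
}
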