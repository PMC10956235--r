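#' Dose-at-volume statistic D_x%
#'
#' The minimum dose received by the hottest `x` percent of a structure's
#' volume, computed by sorting voxel doses in descending order and indexing
#' at `ceiling(x * N / 100)` with no interpolation. `x = 0` gives the maximum
#' voxel dose, `x = 100` the minimum.
#'
#' @param dose 3D dose array in Gy.
#' @param mask logical 3D array, non-empty.
#' @param x volume percentage in \[0, 100\].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dose, mask, x) {
  d <- dose[mask]
  if (!length(d)) stop("empty structure mask")
  if (x < 0 || x > 100) stop("`x` must be in [0, 100]")
  d <- sort(d, decreasing = TRUE)
  idx <- max(1L, ceiling(x * length(d) / 100))
  d[idx]
}

#' Generalized equivalent uniform dose
#'
#' The power mean `((1/N) sum d_i^a)^(1/a)` over the structure's voxel
#' doses. `a = 1` is the mean dose; large `a` approaches the maximum
#' (serial organs), `a` near 1 the mean (parallel organs). Computed with the
#' doses scaled by their maximum so large exponents do not overflow.
#'
#' @param dose 3D dose array in Gy.
#' @param mask logical 3D array, non-empty.
#' @param a gEUD volume-effect parameter (nonzero).
#' @return gEUD in Gy.
#' @export
geud <- function(dose, mask, a) {
  d <- dose[mask]
  if (!length(d)) stop("empty structure mask")
  if (a == 0) stop("`a` must be nonzero")
  dmax <- max(d)
  if (dmax == 0) return(0)
  dmax * mean((d / dmax)^a)^(1 / a)
}

.obj_row <- function(structure, kind, volume_percent, objective_dose, a, priority) {
  data.frame(structure = structure, kind = kind,
             volume_percent = volume_percent,
             objective_dose = pmax(0, objective_dose),
             a = a, priority = priority,
             stringsAsFactors = FALSE)
}

#' Derive the dose-mimicking optimization objective set
#'
#' Builds the full objective table from the prescriptions and the
#' predicted-fluence reference dose, tightened so that fine-tuning is pushed
#' beyond the reference plan:
#' \itemize{
#'   \item PTV-GTV: maximum D_0\% 73.5 Gy (priority 70), minimum D_100\%
#'     71.5 Gy (priority 150);
#'   \item PTV-1-Crop / PTV-2-Crop: maximum D_0\% at prescription + 3 /
#'     + 6 Gy (70); PTV-1 / PTV-2: minimum D_100\% at prescription (150);
#'   \item PTV-LN(L)/(R): maximum D_0\% at prescription + 3 (70), minimum
#'     D_100\% at prescription + 1.5 (150);
#'   \item Brainstem, Spinal cord and their 3 mm expansions: maximum gEUD
#'     (a = 20) at 0.85 x reference gEUD (50);
#'   \item normal parotids: maximum gEUD (a = 3) at 0.75 x reference (50);
#'   \item optic nerves and chiasm: maximum gEUD (a = 1) at the reference
#'     value (50);
#'   \item Ring 2 cm: maximum D_1\%, D_20\%, D_50\% at 0.95 x the reference
#'     statistic and maximum gEUD (a = 15) at 0.95 x reference (all 50);
#'   \item 40 Gy-PTV2: the same three dose-at-volume rows plus maximum gEUD
#'     (a = 10), all at 0.95 x reference (all 50).
#' }
#' Structures absent from the set (possible on degenerate phantoms) are
#' skipped with a warning. Objective doses are floored at 0 Gy.
#'
#' @param ss a [structure_set()] augmented with
#'   [make_auxiliary_structures()].
#' @param reference_dose 3D reference dose array in Gy.
#' @return data.frame of class `objective_set` with columns `structure`,
#'   `kind` (`max_dose_at_volume`, `min_dose_at_volume`, `max_gEUD`),
#'   `volume_percent`, `objective_dose` (Gy), `a`, `priority`.
#' @export
derive_objectives <- function(ss, reference_dose) {
  px <- ss$prescriptions
  rows <- list()
  have <- function(nm) {
    ok <- nm %in% names(ss$masks) && any(ss$masks[[nm]])
    if (!ok) warning(sprintf("structure '%s' missing or empty; objective skipped", nm))
    ok
  }
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  if (have("PTV-GTV")) {
    add(.obj_row("PTV-GTV", "max_dose_at_volume", 0, 73.5, NA, 70))
    add(.obj_row("PTV-GTV", "min_dose_at_volume", 100, 71.5, NA, 150))
  }
  if (have("PTV-1-Crop"))
    add(.obj_row("PTV-1-Crop", "max_dose_at_volume", 0, px[["PTV-1"]] + 3, NA, 70))
  if (have("PTV-1"))
    add(.obj_row("PTV-1", "min_dose_at_volume", 100, px[["PTV-1"]], NA, 150))
  if (have("PTV-2-Crop"))
    add(.obj_row("PTV-2-Crop", "max_dose_at_volume", 0, px[["PTV-2"]] + 6, NA, 70))
  if (have("PTV-2"))
    add(.obj_row("PTV-2", "min_dose_at_volume", 100, px[["PTV-2"]], NA, 150))
  for (ln in c("PTV-LN(L)", "PTV-LN(R)")) {
    if (have(ln)) {
      add(.obj_row(ln, "max_dose_at_volume", 0, px[[ln]] + 3, NA, 70))
      add(.obj_row(ln, "min_dose_at_volume", 100, px[[ln]] + 1.5, NA, 150))
    }
  }
  geud_rows <- list(
    list("Brainstem", 20, 0.85), list("Brainstem 3 mm", 20, 0.85),
    list("Spinal cord", 20, 0.85), list("Spinal cord 3 mm", 20, 0.85),
    list("Left normal parotid", 3, 0.75), list("Right normal parotid", 3, 0.75),
    list("Left optic nerve", 1, 1), list("Right optic nerve", 1, 1),
    list("Chiasm", 1, 1)
  )
  for (gr in geud_rows) {
    nm <- gr[[1]]
    if (have(nm)) {
      ref <- geud(reference_dose, ss$masks[[nm]], gr[[2]])
      add(.obj_row(nm, "max_gEUD", NA, gr[[3]] * ref, gr[[2]], 50))
    }
  }
  spill <- list(list("Ring 2 cm", 15), list("40 Gy-PTV2", 10))
  for (sr in spill) {
    nm <- sr[[1]]
    if (have(nm)) {
      for (xv in c(1, 20, 50)) {
        ref <- dose_at_volume(reference_dose, ss$masks[[nm]], xv)
        add(.obj_row(nm, "max_dose_at_volume", xv, 0.95 * ref, NA, 50))
      }
      refg <- geud(reference_dose, ss$masks[[nm]], sr[[2]])
      add(.obj_row(nm, "max_gEUD", NA, 0.95 * refg, sr[[2]], 50))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("objective_set", "data.frame")
  out
}

#' @export
print.objective_set <- function(x, ...) {
  cat(sprintf("<objective_set> %d objectives\n", nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write an objective set as a human-readable table
#'
#' @param objectives an [derive_objectives()] result.
#' @param path output file; CSV with one row per objective.
#' @export
write_objectives <- function(objectives, path) {
  utils::write.csv(as.data.frame(objectives), path, row.names = FALSE)
  invisible(path)
}
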