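#' Cumulative dose-volume histogram of a structure
#'
#' @param dose 3D dose array in Gy.
#' @param mask logical 3D array, non-empty.
#' @param bin_gy dose-axis bin width in Gy, default 0.1. The curve is the
#'   fraction of structure volume receiving at least each axis dose; summary
#'   metrics elsewhere are computed from raw voxel doses, not this binned
#'   curve.
#' @return data.frame with columns `dose` (Gy) and `volume` (fraction).
#' @export
dvh_curve <- function(dose, mask, bin_gy = 0.1) {
  d <- dose[mask]
  if (!length(d)) stop("empty structure mask")
  axis <- seq(0, max(d) + bin_gy, by = bin_gy)
  vol <- vapply(axis, function(t) mean(d >= t), 0)
  data.frame(dose = axis, volume = vol)
}

#' Conformity index
#'
#' `CI = TV_RI / TV`: the fraction of the target volume covered by the
#' prescription dose. Ranges from 0 to 1; higher is more conformal coverage.
#'
#' @param dose 3D dose array in Gy.
#' @param target logical target mask, non-empty.
#' @param px prescription dose in Gy.
#' @return CI in \[0, 1\].
#' @export
conformity_index <- function(dose, target, px) {
  d <- dose[target]
  if (!length(d)) stop("empty target mask")
  mean(d >= px)
}

#' Homogeneity index
#'
#' `HI = (D_5% - D_95%) / px` under the sort-index dose-at-volume
#' convention; lower values mean a more homogeneous target dose.
#'
#' @param dose 3D dose array in Gy.
#' @param target logical target mask, non-empty.
#' @param px prescription dose in Gy (> 0).
#' @return dimensionless HI.
#' @export
homogeneity_index <- function(dose, target, px) {
  if (px <= 0) stop("`px` must be > 0")
  (dose_at_volume(dose, target, 5) - dose_at_volume(dose, target, 95)) / px
}

#' Per-structure plan-quality metric table
#'
#' For each target: D_2\%, D_98\%, CI and HI (against its prescription); for
#' each organ at risk on the roster: D_max (point maximum), D_mean and
#' D_median (D_50\% under the sort-index convention). Structures missing
#' from the set appear with `NA` values rather than being dropped.
#'
#' @param dose 3D dose array in Gy.
#' @param ss a [structure_set()].
#' @param mu total plan monitor units (carried into the table as metric
#'   `MU` on structure `Plan`).
#' @return data.frame of class `plan_metrics` with columns `structure`,
#'   `metric`, `value`.
#' @export
summarize_plan <- function(dose, ss, mu = NA_real_) {
  rows <- list()
  add <- function(structure, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      structure = structure, metric = metric, value = value,
      stringsAsFactors = FALSE)
  for (nm in ptv_names()) {
    m <- ss$masks[[nm]]
    ok <- !is.null(m) && any(m)
    px <- ss$prescriptions[[nm]]
    add(nm, "D_2%", if (ok) dose_at_volume(dose, m, 2) else NA_real_)
    add(nm, "D_98%", if (ok) dose_at_volume(dose, m, 98) else NA_real_)
    add(nm, "CI", if (ok && !is.null(px)) conformity_index(dose, m, px) else NA_real_)
    add(nm, "HI", if (ok && !is.null(px)) homogeneity_index(dose, m, px) else NA_real_)
  }
  for (nm in oar_roster()) {
    m <- ss$masks[[nm]]
    ok <- !is.null(m) && any(m)
    add(nm, "D_max", if (ok) max(dose[m]) else NA_real_)
    add(nm, "D_mean", if (ok) mean(dose[m]) else NA_real_)
    add(nm, "D_median", if (ok) dose_at_volume(dose, m, 50) else NA_real_)
  }
  add("Plan", "MU", mu)
  out <- do.call(rbind, rows)
  class(out) <- c("plan_metrics", "data.frame")
  out
}

#' Paired comparison of two arms of plan metrics
#'
#' For every (structure, metric) pair present in both arms: mean and
#' standard deviation per arm, the two-sided paired Wilcoxon signed-rank
#' p-value (normal approximation; `NA` below 5 pairs, 1 when every paired
#' difference is zero) and a significance flag at 0.05.
#'
#' @param metrics_a,metrics_b lists of [summarize_plan()] tables, paired by
#'   position (same cases, same length).
#' @param alpha significance level, default 0.05.
#' @return data.frame with columns `structure`, `metric`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `p_value`, `significant`.
#' @export
compare_plans <- function(metrics_a, metrics_b, alpha = 0.05) {
  if (length(metrics_a) != length(metrics_b))
    stop("arms have different numbers of paired cases")
  n <- length(metrics_a)
  if (!n) stop("no cases to compare")
  key <- metrics_a[[1]][, c("structure", "metric")]
  va <- sapply(metrics_a, function(m) m$value)
  vb <- sapply(metrics_b, function(m) m$value)
  if (n == 1L) { va <- cbind(va); vb <- cbind(vb) }
  out <- data.frame(
    structure = key$structure, metric = key$metric,
    mean_a = rowMeans(va), sd_a = apply(va, 1, stats::sd),
    mean_b = rowMeans(vb), sd_b = apply(vb, 1, stats::sd),
    p_value = NA_real_, significant = FALSE,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    a <- va[i, ]; b <- vb[i, ]
    keep <- is.finite(a) & is.finite(b)
    if (sum(keep) >= 5) {
      dif <- a[keep] - b[keep]
      if (all(dif == 0)) {
        out$p_value[i] <- 1
      } else {
        out$p_value[i] <- suppressWarnings(
          stats::wilcox.test(a[keep], b[keep], paired = TRUE,
                             exact = FALSE)$p.value)
      }
      out$significant[i] <- is.finite(out$p_value[i]) && out$p_value[i] < alpha
    }
  }
  out
}

#' Export a metric table or DVH curves as CSV
#'
#' @param x a [summarize_plan()] or [compare_plans()] table, or a named list
#'   of [dvh_curve()] data.frames (bound with a `structure` column).
#' @param path output file.
#' @export
write_metrics <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    curves <- do.call(rbind, lapply(names(x), function(nm)
      cbind(structure = nm, x[[nm]])))
    utils::write.csv(curves, path, row.names = FALSE)
  }
  invisible(path)
}
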