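#' Convert a fluence map to a step-and-shoot MLC aperture sequence
#'
#' The map is quantized to `levels` equal steps of its per-beam maximum and
#' each leaf-pair profile is decomposed by a unidirectional sweep into
#' single-interval openings; identical consecutive apertures are merged into
#' one segment with the summed MU weight. The decomposition reconstructs the
#' quantized map exactly, and the per-beam total MU equals the sweep lower
#' bound (the maximum over leaf pairs of the total profile increase).
#' Leaf pairs run along the fluence v axis (matrix columns); leaves travel
#' along u (matrix rows). 1 MU is one unit of segment fluence weight.
#'
#' @param f a [fluence_map()].
#' @param levels number of intensity levels (>= 1), default 10.
#' @return An object of class `aperture_sequence`: `segments` (each a list
#'   with `intervals`, an `n_pairs x 2` matrix of first/last open u index
#'   with 0/-1 for a closed pair, and `weight` in MU), `total_MU`, the
#'   quantized map `quantized`, and grid metadata. An all-zero map gives an
#'   empty sequence with 0 MU.
#' @export
sequence_fluence <- function(f, levels = 10L) {
  if (!inherits(f, "fluence_map")) stop("`f` must be a fluence_map")
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  vals <- f$values
  nu <- nrow(vals); nv <- ncol(vals)
  fmax <- max(vals)
  empty <- structure(
    list(beam_index = f$beam_index, segments = list(), total_MU = 0,
         levels = levels, delta = 0, shape = c(nu, nv),
         spacing = f$spacing, gantry_angle = f$gantry_angle,
         quantized = matrix(0, nu, nv)),
    class = "aperture_sequence")
  if (fmax == 0) return(empty)

  delta <- fmax / levels
  h <- matrix(as.integer(round(vals / delta)), nu, nv)
  if (all(h == 0L)) return(empty)

  # unidirectional sweep: unit segment t opens where the cumulative profile
  # increase has reached t and the cumulative decrease has not
  t_total <- 0L
  lefts <- rights <- vector("list", nv)
  for (j in seq_len(nv)) {
    p <- c(0L, h[, j], 0L)
    dif <- diff(p)
    inc <- cumsum(pmax(dif, 0L))   # after column i (entries 1..nu+1)
    dec <- cumsum(pmax(-dif, 0L))
    Tj <- inc[nu + 1L]
    t_total <- max(t_total, Tj)
    if (Tj > 0L) {
      ts <- seq_len(Tj)
      # first u with cumulative increase >= t; first u with decrease >= t
      lefts[[j]] <- findInterval(ts - 1L, inc) + 1L
      rights[[j]] <- findInterval(ts - 1L, dec)
    }
  }
  segs <- vector("list", t_total)
  for (t in seq_len(t_total)) {
    iv <- matrix(c(0L, -1L), nv, 2, byrow = TRUE)
    for (j in seq_len(nv)) {
      if (t <= length(lefts[[j]])) {
        l <- lefts[[j]][t]; r <- rights[[j]][t]
        if (l <= r) iv[j, ] <- c(l, r)
      }
    }
    segs[[t]] <- list(intervals = iv, weight = delta)
  }
  # merge identical consecutive apertures
  merged <- list(segs[[1]])
  if (t_total > 1L) for (t in 2:t_total) {
    last <- merged[[length(merged)]]
    if (identical(segs[[t]]$intervals, last$intervals)) {
      merged[[length(merged)]]$weight <- last$weight + segs[[t]]$weight
    } else merged[[length(merged) + 1L]] <- segs[[t]]
  }
  structure(
    list(beam_index = f$beam_index, segments = merged,
         total_MU = t_total * delta, levels = levels, delta = delta,
         shape = c(nu, nv), spacing = f$spacing,
         gantry_angle = f$gantry_angle, quantized = h * delta),
    class = "aperture_sequence")
}

#' @export
print.aperture_sequence <- function(x, ...) {
  cat(sprintf("<aperture_sequence> beam %d: %d segments, %.3g MU\n",
              x$beam_index, length(x$segments), x$total_MU))
  invisible(x)
}

#' Reconstruct the delivered fluence of an aperture sequence
#'
#' The sum over segments of MU weight times the aperture indicator; the
#' exact inverse of [sequence_fluence()] on quantized maps, and the basis
#' for measuring the fluence loss introduced by leaf sequencing.
#'
#' @param seq an [sequence_fluence()] result.
#' @param shape optional `c(nu, nv)` override; defaults to the sequence's
#'   own grid.
#' @return a [fluence_map()] of the delivered fluence.
#' @export
reconstruct_fluence <- function(seq, shape = NULL) {
  if (is.null(shape)) shape <- seq$shape
  vals <- matrix(0, shape[1], shape[2])
  for (s in seq$segments) {
    iv <- s$intervals
    for (j in seq_len(nrow(iv))) {
      if (iv[j, 1] <= iv[j, 2])
        vals[iv[j, 1]:iv[j, 2], j] <- vals[iv[j, 1]:iv[j, 2], j] + s$weight
    }
  }
  fluence_map(seq$beam_index, vals, seq$spacing, gantry_angle = seq$gantry_angle)
}

#' Assemble the final deliverable plan from aperture sequences
#'
#' Reconstructs the delivered fluence of every beam, computes the final dose
#' and bundles the plan-stage result.
#'
#' @param D an [build_influence()] result.
#' @param sequences list of per-beam [sequence_fluence()] results.
#' @return An object of class `plan_result`: `fluence` (delivered per-beam
#'   maps), `sequences`, `total_MU` (plan sum), `dose` (3D Gy array).
#' @export
finalize_plan <- function(D, sequences) {
  fl <- lapply(sequences, reconstruct_fluence)
  dose <- compute_dose(D, fl)
  structure(
    list(fluence = fl, sequences = sequences,
         total_MU = sum(vapply(sequences, function(s) s$total_MU, 0)),
         dose = dose),
    class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> %d beams, %.4g MU, max dose %.3g Gy\n",
              length(x$sequences), x$total_MU, max(x$dose)))
  invisible(x)
}

#' Serialize aperture sequences to JSON
#'
#' One object per beam: gantry angle, grid, and a list of segments with
#' per-leaf-pair open intervals and MU weight.
#'
#' @param sequences list of [sequence_fluence()] results.
#' @param path output JSON file.
#' @export
write_sequences <- function(sequences, path) {
  out <- lapply(sequences, function(s) {
    list(beam_index = s$beam_index, gantry_angle = s$gantry_angle,
         shape = s$shape, spacing = s$spacing, levels = s$levels,
         total_MU = s$total_MU,
         segments = lapply(s$segments, function(g) {
           list(weight = g$weight,
                first_open = g$intervals[, 1], last_open = g$intervals[, 2])
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
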