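#' Write a fluence map to the plain-text fluence file dialect
#'
#' A self-describing header (format tag, beam index, gantry angle, grid
#' shape, spacing and isocenter-plane origin in mm) followed by a `values`
#' section with one line per u row of the intensity grid. Values are written
#' with 17 significant digits, so write/read round-trips are lossless.
#'
#' @param f a [fluence_map()].
#' @param path output file.
#' @export
write_fluence_file <- function(f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "npcplan-fluence 1",
    sprintf("beam_index %d", f$beam_index),
    if (is.finite(f$gantry_angle)) sprintf("gantry_angle %.17g", f$gantry_angle),
    sprintf("shape %d %d", nrow(f$values), ncol(f$values)),
    sprintf("spacing %.17g %.17g", f$spacing[1], f$spacing[2]),
    sprintf("origin %.17g %.17g",
            f$origin_at_isocenter_plane[1], f$origin_at_isocenter_plane[2]),
    "values"), con)
  for (i in seq_len(nrow(f$values)))
    writeLines(paste(sprintf("%.17g", f$values[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read a fluence file written by [write_fluence_file()]
#'
#' Malformed input (unknown header keys, shape/payload mismatches, negative
#' or non-numeric values) raises an error naming the offending line.
#'
#' @param path input file.
#' @return a [fluence_map()].
#' @export
read_fluence_file <- function(path) {
  lines <- readLines(path)
  perr <- function(ln, msg) stop(sprintf("%s:%d: %s", path, ln, msg), call. = FALSE)
  if (!length(lines) || !startsWith(lines[1], "npcplan-fluence"))
    perr(1, "not an npcplan fluence file")
  hdr <- list()
  ln <- 2L
  while (ln <= length(lines) && lines[ln] != "values") {
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    key <- parts[1]
    if (!key %in% c("beam_index", "gantry_angle", "shape", "spacing", "origin"))
      perr(ln, sprintf("unknown header key '%s'", key))
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(vals))) perr(ln, "non-numeric header value")
    hdr[[key]] <- vals
    ln <- ln + 1L
  }
  if (ln > length(lines)) perr(length(lines), "missing 'values' section")
  for (key in c("beam_index", "shape", "spacing"))
    if (is.null(hdr[[key]])) perr(ln, sprintf("missing header key '%s'", key))
  sh <- as.integer(hdr$shape)
  if (length(sh) != 2L || any(sh < 1L)) perr(ln, "invalid shape")
  first_row <- ln + 1L
  if (length(lines) - ln < sh[1])
    perr(length(lines), sprintf("payload has %d rows, header says %d",
                                length(lines) - ln, sh[1]))
  vals <- matrix(0, sh[1], sh[2])
  for (i in seq_len(sh[1])) {
    lno <- first_row + i - 1L
    row <- suppressWarnings(as.numeric(strsplit(trimws(lines[lno]), "\\s+")[[1]]))
    if (length(row) != sh[2])
      perr(lno, sprintf("row has %d values, header says %d", length(row), sh[2]))
    if (any(is.na(row)) || any(!is.finite(row))) perr(lno, "non-numeric value")
    if (any(row < 0)) perr(lno, "negative fluence value")
    vals[i, ] <- row
  }
  fluence_map(hdr$beam_index, vals, hdr$spacing,
              gantry_angle = if (is.null(hdr$gantry_angle)) NA_real_ else hdr$gantry_angle)
}

.safe_name <- function(nm) gsub("[^A-Za-z0-9_.-]+", "_", nm)

#' Save a planning case as a NIfTI archive
#'
#' Writes a directory containing the density volume and one mask volume per
#' structure as compressed NIfTI files, plus a `case.json` sidecar carrying
#' the structure names, their file names, prescriptions, fraction count,
#' spacing and origin.
#'
#' @param vol a [volume_grid()].
#' @param ss a [structure_set()].
#' @param path output directory (created if absent).
#' @export
save_phantom <- function(vol, ss, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(vol$density, pixdim = vol$spacing),
                     file.path(path, "density.nii.gz"))
  files <- character(0)
  for (nm in names(ss$masks)) {
    fn <- paste0("mask_", .safe_name(nm), ".nii.gz")
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(ss$masks[[nm]]), vol$shape),
                      pixdim = vol$spacing),
      file.path(path, fn))
    files[nm] <- fn
  }
  sidecar <- list(
    format = "npcplan-case 1",
    shape = vol$shape, spacing = vol$spacing, origin = vol$origin,
    structures = as.list(files),
    prescriptions = as.list(ss$prescriptions),
    fractions = ss$fractions)
  jsonlite::write_json(sidecar, file.path(path, "case.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a planning case saved by [save_phantom()]
#'
#' @param path case directory.
#' @return list with `vol` and `ss`, as from [generate_phantom()].
#' @export
load_phantom <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "case.json"))
  spacing <- as.numeric(unlist(sidecar$spacing))
  shape <- as.integer(unlist(sidecar$shape))
  density <- array(as.numeric(RNifti::readNifti(file.path(path, "density.nii.gz"))),
                   shape)
  vol <- volume_grid(density, spacing, origin = as.numeric(unlist(sidecar$origin)))
  masks <- lapply(sidecar$structures, function(fn)
    array(as.numeric(RNifti::readNifti(file.path(path, fn))) > 0.5, shape))
  rx <- unlist(sidecar$prescriptions)
  list(vol = vol,
       ss = structure_set(masks, rx, fractions = sidecar$fractions))
}
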