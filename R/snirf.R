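# SNIRF probe export. SNIRF is an HDF5 container; the HDF5 writing/reading
# itself is delegated to small Python helpers (h5py) shipped with the
# package, with JSON as the intermediate representation.

python_helper <- function(name) {
  p <- system.file("python", name, package = "fnirsprobe")
  if (p == "") stop("bundled python helper not found: ", name)
  p
}

have_snirf_backend <- function() {
  nzchar(Sys.which("python")) &&
    suppressWarnings(system2("python", c("-c", shQuote("import h5py")),
                             stdout = FALSE, stderr = FALSE)) == 0
}

run_python <- function(args) {
  out <- suppressWarnings(system2("python", args, stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("SNIRF backend failed: ", paste(out, collapse = "\n"))
  invisible(out)
}

# Assemble the SNIRF probe structure (R list, JSON-ready) from optode
# coordinates and an enumerated channel set. Each source-detector pair
# expands to one measurement-list entry per wavelength, ordered by
# (source index, detector index, wavelength index).
snirf_probe_structure <- function(coords, channels,
                                  wavelengths = c(735, 850)) {
  stopifnot(inherits(channels, "channel_set"))
  if (nrow(channels) == 0) stop("empty channel set; nothing to export")
  opt <- optode_coordinates(coords)
  src <- opt[opt$role == "source", , drop = FALSE]
  det <- opt[opt$role == "detector", , drop = FALSE]
  src <- src[order(src$id), , drop = FALSE]
  det <- det[order(det$id), , drop = FALSE]
  wl <- sort(unique(wavelengths))
  ml <- data.frame(
    sourceIndex = match(channels$source, src$id),
    detectorIndex = match(channels$detector, det$id),
    stringsAsFactors = FALSE)
  ml <- merge(ml, data.frame(wavelengthIndex = seq_along(wl)))
  ml <- ml[order(ml$sourceIndex, ml$detectorIndex, ml$wavelengthIndex), ,
           drop = FALSE]
  planar <- inherits(coords, "planar_layout")
  list(
    formatVersion = "1.1",
    metaDataTags = list(SubjectID = "probe-only",
                        MeasurementDate = "unknown",
                        MeasurementTime = "unknown",
                        LengthUnit = "mm", TimeUnit = "s",
                        FrequencyUnit = "Hz"),
    probe = list(
      wavelengths = wl,
      sourcePos3D = unname(as.matrix(src[, c("x_mm", "y_mm", "z_mm")])),
      detectorPos3D = unname(as.matrix(det[, c("x_mm", "y_mm", "z_mm")])),
      sourcePos2D = if (planar)
        unname(as.matrix(src[, c("x_mm", "y_mm")])) else NULL,
      detectorPos2D = if (planar)
        unname(as.matrix(det[, c("x_mm", "y_mm")])) else NULL,
      sourceLabels = src$id,
      detectorLabels = det$id),
    measurementList = as.list(ml))  # column-wise JSON arrays
}

#' Export a probe to a SNIRF file
#'
#' Writes a probe-only SNIRF (HDF5) file: probe group with optode positions,
#' wavelengths and labels, and a measurement list enumerating every valid
#' channel at both wavelengths (with a zero-length placeholder data block,
#' as no optical time series is simulated).
#'
#' @param coords a [fold_out_2d()] layout or [estimate_probe_shape()] result
#'   supplying optode coordinates.
#' @param channels an [enumerate_channels()] result.
#' @param path output \code{.snirf} path.
#' @param wavelengths wavelengths in nm (default the module LEDs, 735 and
#'   850).
#' @return the path, invisibly.
#' @export
export_snirf_probe <- function(coords, channels, path,
                               wavelengths = c(735, 850)) {
  if (!have_snirf_backend())
    stop("SNIRF export needs a 'python' with h5py on the PATH")
  st <- snirf_probe_structure(coords, channels, wavelengths)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(st, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  run_python(c(python_helper("snirf_write.py"), shQuote(tmp), shQuote(path)))
  if (!file.exists(path)) stop("SNIRF file was not written: ", path)
  invisible(path)
}

#' Read back a SNIRF probe
#'
#' Independent read path (h5py) returning the probe group and measurement
#' list of a SNIRF file; used to validate exported files.
#'
#' @param path a \code{.snirf} file.
#' @return list with \code{formatVersion}, \code{probe} (positions, labels,
#'   wavelengths), \code{measurementList} data frame.
#' @export
read_snirf_probe <- function(path) {
  if (!have_snirf_backend())
    stop("SNIRF reading needs a 'python' with h5py on the PATH")
  if (!file.exists(path)) stop("no such file: ", path)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  run_python(c(python_helper("snirf_read.py"), shQuote(path), shQuote(tmp)))
  out <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  out$measurementList <- as.data.frame(out$measurementList)
  out
}

#' Required-field validation for a SNIRF probe file
#'
#' Checks the probe-relevant required fields of the SNIRF specification:
#' format version, metadata tags, wavelengths, 3D optode positions, and
#' in-range measurement-list indices.
#'
#' @param path a \code{.snirf} file.
#' @return TRUE invisibly, or an error describing the missing field.
#' @export
validate_snirf_probe <- function(path) {
  s <- read_snirf_probe(path)
  if (is.null(s$formatVersion)) stop("missing /formatVersion")
  for (tag in c("SubjectID", "MeasurementDate", "MeasurementTime",
                "LengthUnit", "TimeUnit", "FrequencyUnit"))
    if (is.null(s$metaDataTags[[tag]]))
      stop("missing metaDataTags/", tag)
  if (is.null(s$probe$wavelengths)) stop("missing probe/wavelengths")
  if (is.null(s$probe$sourcePos3D)) stop("missing probe/sourcePos3D")
  if (is.null(s$probe$detectorPos3D)) stop("missing probe/detectorPos3D")
  ml <- s$measurementList
  if (nrow(ml) == 0) stop("empty measurement list")
  if (any(ml$sourceIndex < 1 | ml$sourceIndex > nrow(s$probe$sourcePos3D)))
    stop("measurementList sourceIndex out of range")
  if (any(ml$detectorIndex < 1 |
          ml$detectorIndex > nrow(s$probe$detectorPos3D)))
    stop("measurementList detectorIndex out of range")
  if (any(ml$wavelengthIndex < 1 |
          ml$wavelengthIndex > length(s$probe$wavelengths)))
    stop("measurementList wavelengthIndex out of range")
  invisible(TRUE)
}
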