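# Probe document JSON and CSV interchange. Millimeters everywhere; world
# frame right-handed with z outward from the scalp.

PROBE_FORMAT <- "fnirsprobe-probe/1"

serialize_module_spec <- function(spec) {
  list(edge_length_mm = spec$edge_length_mm,
       thickness_mm = spec$thickness_mm,
       mass_g = spec$mass_g,
       optodes = lapply(spec$optodes, function(o)
         list(label = o$label, role = o$role, x_mm = o$x_mm, y_mm = o$y_mm,
              wavelengths_nm = o$wavelengths_nm)),
       ports = lapply(spec$ports, function(p)
         list(index = p$index, x_mm = p$x_mm, y_mm = p$y_mm,
              outward_dir = p$outward_dir)))
}

deserialize_module_spec <- function(s) {
  module_spec(
    edge_length_mm = s$edge_length_mm,
    thickness_mm = s$thickness_mm,
    mass_g = s$mass_g,
    optodes = lapply(s$optodes, function(o)
      optode(o$label, o$role, o$x_mm, o$y_mm,
             wavelengths_nm = unlist(o$wavelengths_nm))),
    ports = lapply(s$ports, function(p)
      port(p$index, p$x_mm, p$y_mm, unlist(p$outward_dir))))
}

#' Save a probe document
#'
#' Serializes a topology (plus design parameters) to a schema-stable JSON
#' document that [load_probe()] reads back losslessly; unrecognized
#' top-level fields survive a round trip in an \code{extras} bag.
#'
#' @param topology a [discover_topology()] result.
#' @param path output JSON path.
#' @param sds_max_mm,timing design parameters stored alongside the wiring.
#' @param extras named list of extra fields to preserve.
#' @return the path, invisibly.
#' @export
save_probe <- function(topology, path, sds_max_mm = 35,
                       timing = timing_model(), extras = NULL) {
  stopifnot(inherits(topology, "probe_topology"))
  doc <- list(
    format = PROBE_FORMAT,
    tool = paste0("fnirsprobe ",
                  as.character(utils::packageVersion("fnirsprobe"))),
    modules = lapply(topology$modules, function(m) list(id = m)),
    specs = lapply(topology$specs, serialize_module_spec),
    wiring = lapply(seq_len(nrow(topology$wiring)), function(i)
      as.list(topology$wiring[i, ])),
    reference = topology$reference,
    design = list(sds_max_mm = sds_max_mm,
                  timing = list(t_single_ms = timing$t_single_ms,
                                n_wavelengths = timing$n_wavelengths,
                                include_dark = timing$include_dark)))
  if (!is.null(extras)) doc$extras <- extras
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a probe document
#'
#' @param path JSON path written by [save_probe()] (or hand-authored to the
#'   same schema).
#' @return list with \code{topology} (a [discover_topology()] result),
#'   \code{sds_max_mm}, \code{timing}, \code{extras}.
#' @export
load_probe <- function(path) {
  doc <- jsonlite::read_json(path)
  for (field in c("modules", "wiring", "reference"))
    if (is.null(doc[[field]]))
      stop("probe document missing required field '", field, "'")
  modules <- vapply(doc$modules, function(m) {
    if (is.null(m$id)) stop("probe document field 'modules[].id' missing")
    as.character(m$id)
  }, character(1))
  wiring <- if (length(doc$wiring)) {
    for (i in seq_along(doc$wiring)) {
      for (f in c("a", "port_a", "b", "port_b"))
        if (is.null(doc$wiring[[i]][[f]]))
          stop("probe document field 'wiring[].", f, "' missing")
    }
    wiring_list(
      a = vapply(doc$wiring, function(w) as.character(w$a), character(1)),
      port_a = vapply(doc$wiring, function(w) as.integer(w$port_a),
                      integer(1)),
      b = vapply(doc$wiring, function(w) as.character(w$b), character(1)),
      port_b = vapply(doc$wiring, function(w) as.integer(w$port_b),
                      integer(1)),
      distance_mm = vapply(doc$wiring, function(w)
        if (is.null(w$distance_mm)) 55 else as.numeric(w$distance_mm),
        numeric(1)))
  } else wiring_list()
  specs <- if (!is.null(doc$specs))
    lapply(doc$specs, deserialize_module_spec) else default_module_layout()
  topology <- discover_topology(wiring, modules = modules, specs = specs,
                                reference = as.character(doc$reference))
  timing <- timing_model()
  if (!is.null(doc$design$timing)) {
    tm <- doc$design$timing
    timing <- timing_model(
      t_single_ms = if (is.null(tm$t_single_ms)) 7.5 else tm$t_single_ms,
      n_wavelengths = if (is.null(tm$n_wavelengths)) 2 else tm$n_wavelengths,
      include_dark = if (is.null(tm$include_dark)) TRUE else tm$include_dark)
  }
  list(topology = topology,
       sds_max_mm = if (is.null(doc$design$sds_max_mm)) 35
         else as.numeric(doc$design$sds_max_mm),
       timing = timing,
       extras = doc$extras)
}

#' Read and write IMU frame CSVs
#'
#' Columns: \code{time_s}, \code{module}, \code{qw}, \code{qx}, \code{qy},
#' \code{qz}.
#'
#' @param imu data frame of IMU frames.
#' @param path CSV path.
#' @return `read_imu_csv` returns the data frame; `write_imu_csv` the path,
#'   invisibly.
#' @export
write_imu_csv <- function(imu, path) {
  needed <- c("time_s", "module", "qw", "qx", "qy", "qz")
  if (!all(needed %in% names(imu)))
    stop("IMU frames need columns ", paste(needed, collapse = ", "))
  utils::write.csv(imu[, needed], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  imu <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(module = "character"))
  needed <- c("time_s", "module", "qw", "qx", "qy", "qz")
  if (!all(needed %in% names(imu)))
    stop("IMU CSV needs columns ", paste(needed, collapse = ", "))
  imu
}

#' Read and write optode position CSVs
#'
#' Columns: \code{id} (\code{module:label}), \code{x_mm}, \code{y_mm},
#' \code{z_mm} — the digitizer-export-like interchange format.
#'
#' @param positions data frame of positions (a \code{shape_estimate} is
#'   accepted and its optode table written).
#' @param path CSV path.
#' @return `read_positions_csv` returns the data frame; `write_positions_csv`
#'   the path, invisibly.
#' @export
write_positions_csv <- function(positions, path) {
  if (inherits(positions, "shape_estimate")) {
    positions <- positions$optodes[, c("id", "x_mm", "y_mm", "z_mm")]
  }
  if (!all(c("id", "x_mm", "y_mm", "z_mm") %in% names(positions)))
    stop("positions need columns id, x_mm, y_mm, z_mm")
  utils::write.csv(positions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) {
  pos <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x_mm", "y_mm", "z_mm") %in% names(pos)))
    stop("positions CSV needs columns id, x_mm, y_mm, z_mm")
  pos
}

#' Export a channel list as CSV
#'
#' @param channels an [enumerate_channels()] result.
#' @param path CSV path.
#' @param plan optional [assign_smgs()] plan; adds a \code{group} column.
#' @return the path, invisibly.
#' @export
write_channels_csv <- function(channels, path, plan = NULL) {
  stopifnot(inherits(channels, "channel_set"))
  out <- as.data.frame(channels)
  if (!is.null(plan)) out$group <- plan$group_of[out$source]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
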