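# Channel enumeration under a source-detector separation (SDS) threshold,
# the source conflict graph, spatial multiplexing group (SMG) assignment by
# greedy coloring, and acquisition frame-rate prediction.

optode_coordinates <- function(coords) {
  if (inherits(coords, "planar_layout")) return(layout_optodes(coords))
  if (inherits(coords, "shape_estimate")) {
    o <- coords$optodes
    return(data.frame(module = o$module, label = o$label, role = o$role,
                      x_mm = o$x_mm, y_mm = o$y_mm, z_mm = o$z_mm,
                      id = paste(o$module, o$label, sep = ":"),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(coords) &&
      all(c("module", "label", "role", "x_mm", "y_mm") %in% names(coords))) {
    coords$z_mm <- if ("z_mm" %in% names(coords)) coords$z_mm else 0
    coords$id <- paste(coords$module, coords$label, sep = ":")
    return(coords)
  }
  stop("coords must be a planar_layout, a shape_estimate, or an optode ",
       "data frame with columns module, label, role, x_mm, y_mm[, z_mm]")
}

#' Enumerate valid source-detector channels
#'
#' All (source, detector) pairs across the probe whose Euclidean separation
#' in the supplied coordinate space (2D fold-out or 3D shape estimate) does
#' not exceed the SDS threshold.
#'
#' @param coords a [fold_out_2d()] layout, an [estimate_probe_shape()]
#'   result, or an optode coordinate data frame.
#' @param sds_max_mm SDS threshold in mm (default 35, the standard
#'   short-cable operating threshold); \code{Inf} disables filtering.
#' @return data frame of class \code{"channel_set"} with columns
#'   \code{source}, \code{detector} (global \code{"module:label"} ids),
#'   \code{source_module}, \code{detector_module}, \code{sds_mm},
#'   \code{kind} (\code{"intra"} or \code{"inter"}). The full source and
#'   detector tables are kept as attributes for the conflict graph.
#' @export
enumerate_channels <- function(coords, sds_max_mm = 35) {
  opt <- optode_coordinates(coords)
  src <- opt[opt$role == "source", , drop = FALSE]
  det <- opt[opt$role == "detector", , drop = FALSE]
  out <- data.frame(source = character(), detector = character(),
                    source_module = character(), detector_module = character(),
                    sds_mm = numeric(), kind = character(),
                    stringsAsFactors = FALSE)
  if (nrow(src) && nrow(det)) {
    grid <- expand.grid(s = seq_len(nrow(src)), d = seq_len(nrow(det)))
    dd <- sqrt((src$x_mm[grid$s] - det$x_mm[grid$d])^2 +
               (src$y_mm[grid$s] - det$y_mm[grid$d])^2 +
               (src$z_mm[grid$s] - det$z_mm[grid$d])^2)
    keep <- dd <= sds_max_mm
    out <- data.frame(
      source = src$id[grid$s[keep]], detector = det$id[grid$d[keep]],
      source_module = src$module[grid$s[keep]],
      detector_module = det$module[grid$d[keep]],
      sds_mm = dd[keep],
      kind = ifelse(src$module[grid$s[keep]] == det$module[grid$d[keep]],
                    "intra", "inter"),
      stringsAsFactors = FALSE)
    out <- out[order(out$source, out$detector), , drop = FALSE]
    row.names(out) <- NULL
  }
  class(out) <- c("channel_set", "data.frame")
  attr(out, "sds_max_mm") <- sds_max_mm
  attr(out, "sources") <- src
  attr(out, "detectors") <- det
  out
}

#' Build the source conflict graph
#'
#' Two sources conflict when they cannot be lit simultaneously. Under the
#' default \code{"shared_detector"} rule they conflict iff some detector has
#' a valid channel to both (that detector could not attribute simultaneous
#' light). The alternative \code{"source_distance"} rule conflicts sources
#' closer than a distance threshold.
#'
#' @param channels an [enumerate_channels()] result.
#' @param rule conflict rule, \code{"shared_detector"} (default) or
#'   \code{"source_distance"}.
#' @param distance_mm source-source conflict distance for the
#'   \code{"source_distance"} rule; defaults to the channel set's SDS
#'   threshold.
#' @return an igraph whose vertices are all probe sources.
#' @export
build_conflict_graph <- function(channels,
                                 rule = c("shared_detector",
                                          "source_distance"),
                                 distance_mm = NULL) {
  stopifnot(inherits(channels, "channel_set"))
  rule <- match.arg(rule)
  src <- attr(channels, "sources")
  edges <- character()
  if (rule == "shared_detector") {
    for (d in unique(channels$detector)) {
      ss <- sort(unique(channels$source[channels$detector == d]))
      if (length(ss) >= 2) {
        pr <- utils::combn(ss, 2)
        edges <- c(edges, as.vector(pr))
      }
    }
  } else {
    if (is.null(distance_mm)) distance_mm <- attr(channels, "sds_max_mm")
    if (nrow(src) >= 2) {
      pr <- utils::combn(seq_len(nrow(src)), 2)
      dd <- sqrt((src$x_mm[pr[1, ]] - src$x_mm[pr[2, ]])^2 +
                 (src$y_mm[pr[1, ]] - src$y_mm[pr[2, ]])^2 +
                 (src$z_mm[pr[1, ]] - src$z_mm[pr[2, ]])^2)
      keep <- dd < distance_mm
      edges <- as.vector(rbind(src$id[pr[1, keep]], src$id[pr[2, keep]]))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(src), name = src$id)
  if (length(edges))
    g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

#' Assign spatial multiplexing groups
#'
#' Proper coloring of the source conflict graph by the greedy
#' largest-degree-first heuristic with deterministic tie-breaking by source
#' id: sources in the same group can be illuminated simultaneously.
#'
#' @param graph conflict graph from [build_conflict_graph()].
#' @return object of class \code{"smg_plan"}: \code{group_of} (named integer
#'   vector, group index per source), \code{n_groups}, \code{n_sources},
#'   \code{smr} (spatial multiplexing ratio, sources per group).
#' @export
assign_smgs <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("conflict graph has no sources")
  nm <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  ord <- order(-deg, nm)
  group <- stats::setNames(rep(NA_integer_, n), nm)
  adj <- igraph::as_adj_list(graph)
  for (i in ord) {
    used <- group[nm[as.integer(adj[[i]])]]
    used <- used[!is.na(used)]
    group[i] <- min(setdiff(seq_len(n), used))
  }
  # relabel groups in order of first appearance by source id for stable output
  relabel <- stats::setNames(seq_along(unique(group[sort(nm)])),
                             unique(group[sort(nm)]))
  group <- stats::setNames(as.integer(relabel[as.character(group)]), nm)
  structure(list(group_of = group,
                 n_groups = length(unique(group)),
                 n_sources = n,
                 smr = n / length(unique(group))),
            class = "smg_plan")
}

# Exact chromatic number by branch-and-bound with new-color symmetry
# breaking (a vertex may open at most one new color); test oracle for small
# graphs (<= 20 sources).
exact_chromatic_number <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) return(0L)
  ord <- order(-igraph::degree(graph))
  adj_raw <- igraph::as_adj_list(graph)
  rank <- integer(n); rank[ord] <- seq_len(n)
  adj <- lapply(ord, function(v) rank[as.integer(adj_raw[[v]])])
  best <- n
  colr <- rep(NA_integer_, n)
  recurse <- function(i, n_used) {
    if (n_used >= best) return(invisible())
    if (i > n) {
      best <<- n_used
      return(invisible())
    }
    for (col in seq_len(min(n_used + 1, best - 1))) {
      if (!any(colr[adj[[i]]] == col, na.rm = TRUE)) {
        colr[i] <<- col
        recurse(i + 1, max(n_used, col))
        colr[i] <<- NA_integer_
      }
    }
    invisible()
  }
  recurse(1, 0)
  best
}

#' Acquisition timing model
#'
#' One illumination slot serves every channel looking at the active
#' source(s): \code{t_slot = n_wavelengths * t_single * (2 if dark frames
#' are interleaved)} — 30 ms at the defaults (7.5 ms single-wavelength
#' acquisition, two wavelengths, dark measurement per slot).
#'
#' @param t_single_ms single-channel single-wavelength acquisition time in ms.
#' @param n_wavelengths wavelengths per source.
#' @param include_dark interleave a dark measurement per wavelength.
#' @return object of class \code{"timing_model"} with derived
#'   \code{t_slot_ms}.
#' @export
timing_model <- function(t_single_ms = 7.5, n_wavelengths = 2,
                         include_dark = TRUE) {
  stopifnot(t_single_ms > 0, n_wavelengths >= 1)
  structure(list(t_single_ms = t_single_ms,
                 n_wavelengths = as.integer(n_wavelengths),
                 include_dark = isTRUE(include_dark),
                 t_slot_ms = n_wavelengths * t_single_ms *
                   (if (isTRUE(include_dark)) 2 else 1)),
            class = "timing_model")
}

#' Predict full-frame acquisition rate
#'
#' The frame rate is inversely proportional to the number of sequential
#' illumination slots: the source count in sequential mode, the SMG count in
#' spatially multiplexed mode.
#'
#' @param count number of illumination slots per frame (sources or groups).
#' @param timing a [timing_model()].
#' @return frame rate in Hz (unrounded).
#' @export
frame_rate <- function(count, timing = timing_model()) {
  stopifnot(inherits(timing, "timing_model"))
  if (!is.numeric(count) || count <= 0) stop("slot count must be positive")
  1000 / (count * timing$t_slot_ms)
}

#' Full probe design report
#'
#' Runs the design pipeline — fold-out, channel enumeration, conflict graph,
#' SMG assignment, frame rates — and returns a JSON-serializable report.
#' Display rates are rounded to 2 significant figures; raw values retained.
#'
#' @param topology a [discover_topology()] result.
#' @param sds_max_mm SDS threshold in mm (default 35).
#' @param timing a [timing_model()].
#' @param layout optional precomputed [fold_out_2d()] layout or
#'   [estimate_probe_shape()] result to enumerate channels in 3D.
#' @param rule conflict rule, see [build_conflict_graph()].
#' @return list of class \code{"probe_report"}.
#' @export
probe_report <- function(topology, sds_max_mm = 35,
                         timing = timing_model(), layout = NULL,
                         rule = "shared_detector") {
  stopifnot(inherits(topology, "probe_topology"))
  if (length(topology$modules) == 0) stop("empty probe")
  if (is.null(layout)) layout <- fold_out_2d(topology)
  channels <- enumerate_channels(layout, sds_max_mm)
  if (nrow(channels) == 0) stop("no valid channels under the SDS threshold")
  graph <- build_conflict_graph(channels, rule = rule)
  plan <- assign_smgs(graph)
  dens <- channel_density_probe(channels, topology)
  seq_rate <- frame_rate(plan$n_sources, timing)
  mux_rate <- frame_rate(plan$n_groups, timing)
  structure(list(
    n_modules = length(topology$modules),
    n_channels = nrow(channels),
    n_intra = sum(channels$kind == "intra"),
    n_inter = sum(channels$kind == "inter"),
    n_sources = plan$n_sources,
    n_detectors = nrow(attr(channels, "detectors")),
    n_groups = plan$n_groups,
    smr = plan$smr,
    improvement_ratio = plan$smr,
    rate_sequential_hz = seq_rate,
    rate_multiplexed_hz = mux_rate,
    rate_sequential_hz_display = signif(seq_rate, 2),
    rate_multiplexed_hz_display = signif(mux_rate, 2),
    sds_max_mm = sds_max_mm,
    t_slot_ms = timing$t_slot_ms,
    channel_density_per_pair_cm2 = dens$per_pair_cm2,
    channel_density_per_wavelength_cm2 = dens$per_wavelength_cm2,
    channel_density_note = paste(
      "per_pair counts each dual-wavelength SD pair once;",
      "per_wavelength counts each wavelength separately"),
    groups = plan$group_of), class = "probe_report")
}

channel_density_probe <- function(channels, topology) {
  area <- sum(vapply(topology$specs, module_area, numeric(1)))
  src <- attr(channels, "sources")
  n_wl <- 2
  if (nrow(src)) {
    spec1 <- topology$specs[[src$module[1]]]
    wls <- unique(unlist(lapply(
      Filter(function(o) o$role == "source", spec1$optodes),
      function(o) o$wavelengths_nm)))
    if (length(wls)) n_wl <- length(wls)
  }
  list(per_pair_cm2 = nrow(channels) / area,
       per_wavelength_cm2 = nrow(channels) * n_wl / area)
}

#' @export
print.probe_report <- function(x, ...) {
  cat(sprintf(
    paste0("<probe_report> %d modules | %d channels (%d intra, %d inter)\n",
           "  %d sources in %d SMGs (SMR %.2f)\n",
           "  sequential %.3g Hz, multiplexed %.3g Hz\n"),
    x$n_modules, x$n_channels, x$n_intra, x$n_inter,
    x$n_sources, x$n_groups, x$smr,
    x$rate_sequential_hz_display, x$rate_multiplexed_hz_display))
  invisible(x)
}

#' @export
print.smg_plan <- function(x, ...) {
  cat(sprintf("<smg_plan> %d sources in %d groups (SMR %.2f)\n",
              x$n_sources, x$n_groups, x$smr))
  invisible(x)
}
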