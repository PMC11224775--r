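# Diamond (dual-equilateral-triangle) optode module geometry.
#
# Module-local frame: origin at the module center, x along the short axis,
# y along the long axis, z the outward normal (right-handed). Units are mm.
# The diamond outline is the rhombus with vertices (+-e/2, 0) on the short
# axis and (0, +-e*sqrt(3)/2) on the long axis, i.e. two equilateral
# triangles of side e joined on their shared short diagonal.

#' Construct an optode
#'
#' @param label optode label, unique within a module (e.g. \code{"S1"},
#'   \code{"D2"}).
#' @param role \code{"source"} or \code{"detector"}.
#' @param x_mm,y_mm module-local coordinates in mm.
#' @param wavelengths_nm emission wavelengths in nm; defaults to the module's
#'   dual-wavelength LEDs \code{c(735, 850)} for sources, none for detectors.
#' @return an object of class \code{"optode"}.
#' @export
optode <- function(label, role = c("source", "detector"), x_mm, y_mm,
                   wavelengths_nm = NULL) {
  role <- match.arg(role)
  if (is.null(wavelengths_nm))
    wavelengths_nm <- if (role == "source") c(735, 850) else numeric()
  structure(list(label = as.character(label), role = role,
                 x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                 wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "optode")
}

#' Construct an inter-module connector port
#'
#' @param index port index 1..4.
#' @param x_mm,y_mm module-local anchor coordinates in mm.
#' @param outward_dir unit 2-vector, the direction a cable leaves the module.
#' @return an object of class \code{"port"}.
#' @export
port <- function(index, x_mm, y_mm, outward_dir) {
  outward_dir <- as.numeric(outward_dir)
  if (length(outward_dir) != 2 || abs(sqrt(sum(outward_dir^2)) - 1) > 1e-9)
    stop("outward_dir must be a unit 2-vector")
  structure(list(index = as.integer(index), x_mm = as.numeric(x_mm),
                 y_mm = as.numeric(y_mm), outward_dir = outward_dir),
            class = "port")
}

#' Construct a module specification
#'
#' Validates that optode labels are unique, that all optodes lie inside the
#' diamond outline, and that port indices are unique.
#'
#' @param edge_length_mm diamond edge length in mm (default 50).
#' @param thickness_mm module thickness in mm (default 5); used by the
#'   conformity analysis, where the expected optode-to-sphere-center distance
#'   is the surface radius plus this thickness.
#' @param optodes list of [optode()] objects.
#' @param ports list of four [port()] objects; defaults to ports at the four
#'   diamond edge midpoints with outward edge normals.
#' @param mass_g module mass metadata in grams (default 18).
#' @return an object of class \code{"module_spec"}.
#' @export
module_spec <- function(edge_length_mm = 50, thickness_mm = 5,
                        optodes = list(), ports = NULL, mass_g = 18) {
  if (!is.numeric(edge_length_mm) || edge_length_mm <= 0)
    stop("edge_length_mm must be positive")
  if (is.null(ports)) ports <- default_ports(edge_length_mm)
  if (length(ports) != 4L)
    stop("a module has exactly 4 connector ports")
  idx <- vapply(ports, function(p) p$index, integer(1))
  if (anyDuplicated(idx)) stop("port indices must be unique")
  labels <- vapply(optodes, function(o) o$label, character(1))
  if (anyDuplicated(labels)) stop("optode labels must be unique")
  half_w <- edge_length_mm / 2
  half_h <- edge_length_mm * sqrt(3) / 2
  for (o in optodes) {
    if (abs(o$x_mm) / half_w + abs(o$y_mm) / half_h > 1 + 1e-9)
      stop(sprintf("optode %s at (%.2f, %.2f) lies outside the diamond",
                   o$label, o$x_mm, o$y_mm))
  }
  structure(list(edge_length_mm = edge_length_mm,
                 thickness_mm = thickness_mm,
                 optodes = optodes,
                 ports = ports[order(idx)],
                 mass_g = mass_g),
            class = "module_spec")
}

# Ports at the four edge midpoints, outward direction = edge outward normal.
# Port 1 is the +x,+y edge, then clockwise when viewed from +z:
# 1 -> (+,+), 2 -> (+,-), 3 -> (-,-), 4 -> (-,+); opposite pairs 1-3, 2-4.
default_ports <- function(edge_length_mm = 50) {
  hx <- edge_length_mm / 4          # edge midpoint x
  hy <- edge_length_mm * sqrt(3) / 4
  nx <- sqrt(3) / 2                 # outward edge normal components
  ny <- 1 / 2
  list(port(1,  hx,  hy, c( nx,  ny)),
       port(2,  hx, -hy, c( nx, -ny)),
       port(3, -hx, -hy, c(-nx, -ny)),
       port(4, -hx,  hy, c(-nx,  ny)))
}

opposite_port <- function(index) ((index + 1L) %% 4L) + 1L

#' Canonical diamond module layout
#'
#' The module carries three dual-wavelength sources and two detectors whose
#' six source-detector separations form the multiset \{8, 24.5 x4, 30\} mm.
#' Exact coordinates are fixed (the distance constraints plus symmetry about
#' the long axis and collinearity of S3, D1, D2 on it determine them): D1 and
#' D2 sit at (0, +-11), S3 at (0, 19), and S1/S2 at
#' (+-sqrt(24.5^2 - 11^2), 0) on the short axis.
#'
#' @param edge_length_mm diamond edge length in mm (default 50).
#' @return a [module_spec()].
#' @export
default_module_layout <- function(edge_length_mm = 50) {
  xs <- sqrt(24.5^2 - 11^2)  # 21.8918: puts S1/S2 at 24.5 mm from D1 and D2
  module_spec(
    edge_length_mm = edge_length_mm,
    optodes = list(
      optode("S1", "source", -xs, 0),
      optode("S2", "source",  xs, 0),
      optode("S3", "source",   0, 19),
      optode("D1", "detector", 0, 11),
      optode("D2", "detector", 0, -11)))
}

#' Intra-module channels
#'
#' One channel per (source, detector) pair within the module, with its 2D
#' Euclidean separation.
#'
#' @param spec a [module_spec()].
#' @return data frame with columns \code{source}, \code{detector},
#'   \code{sds_mm}, ordered by source then detector label.
#' @export
intra_module_channels <- function(spec) {
  stopifnot(inherits(spec, "module_spec"))
  src <- Filter(function(o) o$role == "source", spec$optodes)
  det <- Filter(function(o) o$role == "detector", spec$optodes)
  out <- data.frame(source = character(), detector = character(),
                    sds_mm = numeric(), stringsAsFactors = FALSE)
  for (s in src) for (d in det) {
    out <- rbind(out, data.frame(
      source = s$label, detector = d$label,
      sds_mm = sqrt((s$x_mm - d$x_mm)^2 + (s$y_mm - d$y_mm)^2),
      stringsAsFactors = FALSE))
  }
  out[order(out$source, out$detector), , drop = FALSE]
}

#' Diamond module area
#'
#' Area of the rhombus outline, \code{2 * (sqrt(3)/4) * edge^2}.
#'
#' @param spec a [module_spec()], or a numeric edge length in mm.
#' @return area in cm^2.
#' @export
module_area <- function(spec) {
  edge <- if (inherits(spec, "module_spec")) spec$edge_length_mm
          else as.numeric(spec)
  if (!is.finite(edge) || edge <= 0) stop("edge length must be positive")
  2 * (sqrt(3) / 4) * edge^2 / 100  # mm^2 -> cm^2
}

#' Channel density of a module
#'
#' The per-area channel count is convention-dependent: a dual-wavelength
#' source-detector pair can be counted once (6 pairs for the canonical
#' module) or once per wavelength (12). Both are reported; neither is chosen
#' as "the" density.
#'
#' @param spec a [module_spec()].
#' @return list with \code{per_pair_cm2} and \code{per_wavelength_cm2}.
#' @export
channel_density <- function(spec) {
  ch <- intra_module_channels(spec)
  area <- module_area(spec)
  n_wl <- max(1L, length(unique(unlist(
    lapply(Filter(function(o) o$role == "source", spec$optodes),
           function(o) o$wavelengths_nm)))))
  list(per_pair_cm2 = nrow(ch) / area,
       per_wavelength_cm2 = nrow(ch) * n_wl / area)
}

#' @export
print.module_spec <- function(x, ...) {
  roles <- vapply(x$optodes, function(o) o$role, character(1))
  cat(sprintf(
    "<module_spec> edge %.1f mm, %d sources, %d detectors, %d ports\n",
    x$edge_length_mm, sum(roles == "source"), sum(roles == "detector"),
    length(x$ports)))
  invisible(x)
}

module_optode_xy <- function(spec) {
  data.frame(
    label = vapply(spec$optodes, function(o) o$label, character(1)),
    role = vapply(spec$optodes, function(o) o$role, character(1)),
    x_mm = vapply(spec$optodes, function(o) o$x_mm, numeric(1)),
    y_mm = vapply(spec$optodes, function(o) o$y_mm, numeric(1)),
    stringsAsFactors = FALSE)
}
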