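# Synthetic placements of probes on analytic surfaces with exact ground
# truth. Modules are walked along geodesics of the surface so that the
# piece-wise spherical model is exact on a sphere, cleanly separating
# algorithm error from model mismatch in tests.

#' Analytic surfaces for synthetic placements
#'
#' @param radius_mm sphere radius in mm (> 0).
#' @param center sphere center (mm 3-vector).
#' @return object of class \code{"synthetic_surface"}.
#' @export
surface_sphere <- function(radius_mm, center = c(0, 0, 0)) {
  stopifnot(is.numeric(radius_mm), radius_mm > 0)
  structure(list(kind = "sphere", radius_mm = radius_mm,
                 center = as.numeric(center)),
            class = "synthetic_surface")
}

#' @rdname surface_sphere
#' @param origin plane origin (mm 3-vector); the plane is z = origin[3] with
#'   outward normal +z.
#' @export
surface_plane <- function(origin = c(0, 0, 0)) {
  structure(list(kind = "plane", center = as.numeric(origin)),
            class = "synthetic_surface")
}

#' Place a probe on a synthetic surface
#'
#' The reference module is placed at the anchor point (the top of the sphere
#' or the plane origin by default) with its local frame aligned to the
#' surface: local z maps to the outward normal. Each neighbor is then placed
#' by walking a geodesic of the edge's center distance in the world
#' direction of the connecting port; its quaternion is constructed so that
#' its own connecting port points back along the geodesic and its z axis
#' maps to the surface normal at the arrival point.
#'
#' @param topology a [discover_topology()] result.
#' @param surface a [surface_sphere()] or [surface_plane()].
#' @param heading_deg optional global rotation of the whole placement about
#'   the anchor normal, emulating an arbitrary magnetic-heading reference;
#'   shape recovery is invariant to it.
#' @param seed optional integer; stored in the placement for provenance
#'   (the placement itself is deterministic).
#' @return object of class \code{"probe_placement"}: \code{modules} (centers,
#'   normals, quaternions), \code{optodes} (world positions with
#'   \code{id = module:label}), \code{surface}, \code{seed}.
#' @export
place_on_surface <- function(topology, surface, heading_deg = 0,
                             seed = NULL) {
  stopifnot(inherits(topology, "probe_topology"),
            inherits(surface, "synthetic_surface"))
  sphere <- surface$kind == "sphere"
  if (sphere) {
    R <- surface$radius_mm
    if (any(topology$wiring$distance_mm / R >= pi))
      stop("an edge arc exceeds pi * radius; modules cannot be placed")
  }
  heading <- quat_from_axis_angle(c(0, 0, 1), heading_deg * pi / 180)
  anchor <- if (sphere) surface$center + c(0, 0, R) else surface$center
  quats <- list(); centers <- list()
  centers[[topology$reference]] <- anchor
  quats[[topology$reference]] <- heading
  edges <- bfs_tree_edges(topology)
  for (i in seq_len(NROW(edges))) {
    e <- edges[i, ]
    p0 <- centers[[e$from]]
    q0 <- quats[[e$from]]
    t0 <- port_tangent(topology$specs[[e$from]], e$port_from, q0)
    if (sphere) {
      n0 <- unit3(p0 - surface$center)
      theta <- e$distance_mm / R
      p1 <- surface$center + cos(theta) * (p0 - surface$center) +
        sin(theta) * R * t0
      n1 <- unit3(p1 - surface$center)
      t1 <- cos(theta) * t0 - sin(theta) * n0   # transported travel direction
    } else {
      p1 <- p0 + e$distance_mm * t0
      n1 <- c(0, 0, 1)
      t1 <- t0
    }
    # neighbor frame: its connecting port points back (-t1), z maps to n1
    back_local <- topology$specs[[e$to]]$ports[[e$port_to]]$outward_dir
    quats[[e$to]] <- frame_quaternion(c(back_local, 0), -t1, n1)
    centers[[e$to]] <- p1
  }
  optodes <- NULL
  for (m in topology$modules) {
    xy <- module_optode_xy(topology$specs[[m]])
    q <- quats[[m]]; ctr <- centers[[m]]
    pos <- matrix(NA_real_, nrow(xy), 3)
    for (i in seq_len(nrow(xy))) {
      v <- c(xy$x_mm[i], xy$y_mm[i])
      d <- sqrt(sum(v^2))
      if (d < 1e-12) {
        pos[i, ] <- ctr
      } else if (sphere) {
        n <- unit3(ctr - surface$center)
        t_hat <- quat_rotate(q, c(v / d, 0))
        pos[i, ] <- ctr + R * ((cos(d / R) - 1) * n + sin(d / R) * t_hat)
      } else {
        pos[i, ] <- ctr + quat_rotate(q, c(v, 0))
      }
    }
    optodes <- rbind(optodes, data.frame(
      module = m, label = xy$label, role = xy$role,
      x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
      id = paste(m, xy$label, sep = ":"), stringsAsFactors = FALSE))
  }
  mods <- data.frame(
    module = topology$modules,
    cx_mm = vapply(topology$modules, function(m) centers[[m]][1], numeric(1)),
    cy_mm = vapply(topology$modules, function(m) centers[[m]][2], numeric(1)),
    cz_mm = vapply(topology$modules, function(m) centers[[m]][3], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(modules = mods,
                 quaternions = quats[topology$modules],
                 optodes = optodes,
                 surface = surface,
                 topology = topology,
                 seed = seed),
            class = "probe_placement")
}

# Quaternion mapping the module-local orthonormal pair (u_local -> u_world,
# z -> n_world); the third axis follows by right-handedness.
frame_quaternion <- function(u_local, u_world, n_world) {
  u_local <- unit3(u_local)
  u_world <- unit3(u_world - sum(u_world * n_world) * n_world)
  e3 <- c(0, 0, 1)
  basis_local <- cbind(u_local, cross3(e3, u_local), e3)
  basis_world <- cbind(u_world, cross3(n_world, u_world), n_world)
  quat_from_matrix(basis_world %*% t(basis_local))
}

#' Ground-truth IMU frames, optionally with orientation noise
#'
#' Composes each ground-truth quaternion with a random small rotation:
#' uniformly distributed axis, angle drawn from Normal(0, sigma).
#'
#' @param placement a [place_on_surface()] result.
#' @param sigma_deg orientation noise standard deviation in degrees (>= 0).
#' @param seed integer seed; required for reproducibility when
#'   \code{sigma_deg > 0}.
#' @return data frame with columns \code{time_s}, \code{module}, \code{qw},
#'   \code{qx}, \code{qy}, \code{qz} (one frame at t = 0).
#' @export
add_orientation_noise <- function(placement, sigma_deg = 0, seed = NULL) {
  stopifnot(inherits(placement, "probe_placement"))
  if (!is.numeric(sigma_deg) || sigma_deg < 0)
    stop("sigma_deg must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  quats <- placement$quaternions
  if (sigma_deg > 0) {
    quats <- lapply(quats, function(q) {
      axis <- stats::rnorm(3)
      while (sum(axis^2) < 1e-12) axis <- stats::rnorm(3)
      angle <- stats::rnorm(1, 0, sigma_deg * pi / 180)
      quat_multiply(quat_from_axis_angle(axis, angle), q)
    })
  }
  data.frame(
    time_s = 0,
    module = names(quats),
    qw = vapply(quats, `[`, numeric(1), 1),
    qx = vapply(quats, `[`, numeric(1), 2),
    qy = vapply(quats, `[`, numeric(1), 3),
    qz = vapply(quats, `[`, numeric(1), 4),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Emulate digitizer readings of the optode positions
#'
#' Ground-truth optode positions with isotropic Gaussian jitter, optionally
#' repeated (a digitizer protocol typically averages several passes).
#'
#' @param placement a [place_on_surface()] result.
#' @param jitter_mm per-axis jitter standard deviation in mm (>= 0).
#' @param repeats number of digitization passes (default 1).
#' @param seed integer seed for reproducibility.
#' @param path optional CSV path; written with columns \code{repeat_id},
#'   \code{id}, \code{x_mm}, \code{y_mm}, \code{z_mm}.
#' @return data frame (invisibly when \code{path} is given).
#' @export
emit_digitizer_file <- function(placement, jitter_mm = 0, repeats = 1,
                                seed = NULL, path = NULL) {
  stopifnot(inherits(placement, "probe_placement"),
            is.numeric(jitter_mm), jitter_mm >= 0, repeats >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  truth <- placement$optodes
  out <- NULL
  for (k in seq_len(repeats)) {
    jit <- matrix(stats::rnorm(3 * nrow(truth), 0, jitter_mm), ncol = 3)
    out <- rbind(out, data.frame(
      repeat_id = k, id = truth$id,
      x_mm = truth$x_mm + jit[, 1],
      y_mm = truth$y_mm + jit[, 2],
      z_mm = truth$z_mm + jit[, 3],
      stringsAsFactors = FALSE))
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Average digitizer repeats
#'
#' @param digitized output of [emit_digitizer_file()] with several repeats.
#' @return data frame with one averaged row per optode plus
#'   \code{repeat_sd_mm}, the per-optode standard deviation of the 3D
#'   readings across repeats (pooled over axes).
#' @export
average_digitizer_repeats <- function(digitized) {
  sp <- split(digitized, digitized$id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(id = d$id[1],
               x_mm = mean(d$x_mm), y_mm = mean(d$y_mm), z_mm = mean(d$z_mm),
               repeat_sd_mm = if (nrow(d) > 1)
                 sqrt(mean(c(stats::var(d$x_mm), stats::var(d$y_mm),
                             stats::var(d$z_mm)))) else 0,
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out[order(out$id), , drop = FALSE]
}

#' The V-shaped five-module evaluation probe
#'
#' A five-module probe whose two straight two-cable arms meet at the central
#' tip module (module 3, the reference), the configuration used for
#' conformity and localization-accuracy evaluations on a hemisphere phantom.
#' Arms run through opposite-port (straight) connections; the assumed wiring
#' is ports 4-2 repeatedly for one arm and 1-3 for the other, giving a 120
#' degree opening between the arms.
#'
#' @param distance_mm inter-module center distance in mm (default 55).
#' @return a [discover_topology()] result with reference module "3".
#' @export
v_probe_topology <- function(distance_mm = 55) {
  discover_topology(
    wiring_list(a = c("3", "2", "3", "4"),
                port_a = c(4, 4, 1, 1),
                b = c("2", "1", "4", "5"),
                port_b = c(2, 2, 3, 3),
                distance_mm = distance_mm),
    reference = "3")
}

#' @export
print.probe_placement <- function(x, ...) {
  cat(sprintf("<probe_placement> %d modules on a %s%s\n",
              nrow(x$modules), x$surface$kind,
              if (x$surface$kind == "sphere")
                sprintf(" (R = %g mm)", x$surface$radius_mm) else ""))
  invisible(x)
}
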