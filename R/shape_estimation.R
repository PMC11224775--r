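# Piece-wise spherical 3D shape estimation from per-module orientation
# quaternions, and evaluation against digitized optode positions.
#
# The surface between each pair of adjacent modules is approximated by a
# sphere: the bending angle theta between the module normals and the known
# center-to-center cable length L give its radius r = L / theta, and the
# neighbor's center follows from  p_P = p_R - r (n_R - n_P).  On a common
# sphere of radius R this propagation is exact (p = c + R n for every
# module), which is the primary correctness oracle for the implementation.

FLAT_EPS <- 1e-4  # rad; below this bending angle a pair is treated as flat

#' Module normal from its orientation quaternion
#'
#' The module normal is the quaternion rotation applied to the local outward
#' axis (0, 0, 1).
#'
#' @param q unit quaternion \code{(w, x, y, z)} (module frame to world).
#' @return unit 3-vector.
#' @export
normal_from_quaternion <- function(q) {
  q <- quat_check(q)
  quat_rotate(q, c(0, 0, 1))
}

#' Geodesic rotation angle between two orientations
#'
#' The angle of the relative rotation \code{q_R^-1 q_P}, in \code{[0, pi]};
#' invariant to the quaternion double cover (\code{q} and \code{-q} give 0).
#'
#' @param q_r,q_p unit quaternions.
#' @return angle in radians.
#' @export
rotation_angle <- function(q_r, q_p) {
  q_r <- quat_check(q_r); q_p <- quat_check(q_p)
  rel <- quat_multiply(quat_conjugate(q_r), q_p)
  2 * atan2(sqrt(sum(rel[2:4]^2)), abs(rel[1]))
}

# Bending (swing) angle between module normals. This is the angle that
# enters r = L / theta: the full relative rotation additionally contains
# the in-plane twist imposed by the port wiring (e.g. a connection through
# non-opposite ports), which carries no information about surface curvature.
normal_angle <- function(n_r, n_p) {
  acos(max(-1, min(1, sum(n_r * n_p))))
}

#' Pairwise spherical radius
#'
#' Radius of the local sphere between two adjacent modules,
#' \code{r = L / theta}. Bending angles below \code{eps} indicate a locally
#' flat surface and return \code{Inf}.
#'
#' @param theta bending angle in radians (>= 0).
#' @param l_mm center-to-center distance in mm (> 0).
#' @param eps flat-surface threshold in radians (default 1e-4).
#' @return radius in mm; \code{Inf} flags a flat pair.
#' @export
pairwise_radius <- function(theta, l_mm, eps = FLAT_EPS) {
  if (!is.finite(theta) || theta < 0) stop("theta must be >= 0")
  if (!is.finite(l_mm) || l_mm <= 0) stop("l_mm must be positive")
  if (theta < eps) return(Inf)
  l_mm / theta
}

#' Propagate a module center across one edge
#'
#' Applies \code{p_P = p_R - r (n_R - n_P)}. In the flat limit
#' (\code{r = Inf}, parallel normals) the neighbor is placed at the cable
#' length along the connecting port's world tangent direction instead, which
#' the spherical formula degenerately maps onto \code{p_R}.
#'
#' @param p_r reference-side center (mm 3-vector).
#' @param n_r,n_p unit normals of the two modules.
#' @param r pairwise radius in mm (\code{Inf} = flat).
#' @param l_mm center distance, required in the flat branch.
#' @param tangent world unit vector of the connecting port direction,
#'   required in the flat branch.
#' @return neighbor center (mm 3-vector).
#' @export
propagate_center <- function(p_r, n_r, n_p, r, l_mm = NULL, tangent = NULL) {
  if (is.infinite(r)) {
    if (is.null(l_mm) || is.null(tangent))
      stop("flat propagation needs l_mm and the port tangent direction")
    return(p_r + l_mm * unit3(tangent))
  }
  if (r < 0) stop("radius must be non-negative")
  p_r - r * (n_r - n_p)
}

# World tangent direction of a module's port under its orientation.
port_tangent <- function(spec, port_index, q) {
  d <- spec$ports[[port_index]]$outward_dir
  quat_rotate(q, c(d[1], d[2], 0))
}

as_imu_frameset <- function(imu, modules) {
  if (is.data.frame(imu)) {
    needed <- c("module", "qw", "qx", "qy", "qz")
    if (!all(needed %in% names(imu)))
      stop("IMU frame needs columns module, qw, qx, qy, qz")
    imu <- stats::setNames(
      lapply(seq_len(nrow(imu)),
             function(i) as.numeric(imu[i, c("qw", "qx", "qy", "qz")])),
      as.character(imu$module))
  }
  missing <- setdiff(modules, names(imu))
  if (length(missing))
    stop("missing IMU quaternion for module(s): ",
         paste(missing, collapse = ", "))
  lapply(imu[modules], quat_check)
}

#' Planar constraint for straight module chains
#'
#' Modules wired in a straight line (each interior module entered and left
#' through opposite ports) must lie in a common plane. For each chain, the
#' pairwise planes spanned by the anchor module's normal and each member's
#' normal are averaged (by their plane normals, sign-aligned), and every
#' member normal is projected onto the average plane and renormalized.
#' Chains shorter than three modules are left untouched.
#'
#' @param topology a [discover_topology()] result.
#' @param normals named list of unit normals per module.
#' @return named list of adjusted unit normals.
#' @export
apply_planar_constraint <- function(topology, normals) {
  chains <- straight_chains(topology)
  dist_to_ref <- igraph::distances(topology$graph, v = topology$reference)[1, ]
  for (chain in chains) {
    if (length(chain) < 3) next
    anchor <- chain[which.min(dist_to_ref[chain])]
    n_a <- normals[[anchor]]
    planes <- NULL
    for (m in setdiff(chain, anchor)) {
      cr <- cross3(n_a, normals[[m]])
      if (sqrt(sum(cr^2)) < 1e-12) next  # parallel normals span no plane
      planes <- rbind(planes, unit3(cr))
    }
    if (is.null(planes)) next  # all coplanar-degenerate; nothing to average
    for (i in seq_len(nrow(planes)))  # sign-align before averaging
      if (sum(planes[i, ] * planes[1, ]) < 0) planes[i, ] <- -planes[i, ]
    m_avg <- unit3(colMeans(planes))
    for (m in chain) {
      n <- normals[[m]]
      n_proj <- n - sum(n * m_avg) * m_avg
      if (sqrt(sum(n_proj^2)) < 1e-12) next
      normals[[m]] <- unit3(n_proj)
    }
  }
  normals
}

#' Estimate the 3D probe shape from IMU quaternions
#'
#' Two-step reconstruction. Step 1 propagates module centers breadth-first
#' from the reference module: for each traversed cable the bending angle of
#' the two normals gives the pairwise sphere radius \code{r = L/theta} and
#' the neighbor center follows from \code{p_P = p_R - r (n_R - n_P)}; the
#' planar constraint is then applied to straight chains and the centers are
#' recomputed from the reference with the adjusted normals. Step 2 places
#' each module's optodes on its local sphere (radius = mean of the incident
#' pairwise radii) at the arc length given by their 2D offset from the
#' module center.
#'
#' @param topology a [discover_topology()] result.
#' @param imu named list of unit quaternions per module, or a data frame
#'   with columns \code{module}, \code{qw}, \code{qx}, \code{qy}, \code{qz}.
#' @param planar_constraint apply the straight-chain planar constraint
#'   (default TRUE).
#' @return object of class \code{"shape_estimate"}: \code{modules} (centers
#'   and normals; the reference module center is the origin), \code{edges}
#'   (per-cable theta and radius), \code{optodes} (world positions),
#'   \code{reference}, \code{quaternions}.
#' @export
estimate_probe_shape <- function(topology, imu, planar_constraint = TRUE) {
  stopifnot(inherits(topology, "probe_topology"))
  quats <- as_imu_frameset(imu, topology$modules)
  # resolve the double-cover sign ambiguity towards the reference quaternion
  q_ref <- quats[[topology$reference]]
  quats <- lapply(quats, function(q) if (sum(q * q_ref) < 0) -q else q)
  normals <- lapply(quats, function(q) quat_rotate(q, c(0, 0, 1)))

  centers <- propagate_all_centers(topology, quats, normals)
  if (planar_constraint && length(straight_chains(topology))) {
    normals <- apply_planar_constraint(topology, normals)
    centers <- propagate_all_centers(topology, quats, normals)
  }

  edges <- edge_radii(topology, normals)
  optodes <- NULL
  for (m in topology$modules) {
    r_loc <- local_radius(edges, m)
    op <- project_optodes(centers[[m]], quats[[m]], topology$specs[[m]],
                          r_loc, normal = normals[[m]],
                          warn_isolated = is.na(r_loc))
    op$module <- m
    optodes <- rbind(optodes, op)
  }
  optodes$id <- paste(optodes$module, optodes$label, sep = ":")
  mods <- data.frame(
    module = topology$modules,
    cx_mm = vapply(topology$modules, function(m) centers[[m]][1], numeric(1)),
    cy_mm = vapply(topology$modules, function(m) centers[[m]][2], numeric(1)),
    cz_mm = vapply(topology$modules, function(m) centers[[m]][3], numeric(1)),
    nx = vapply(topology$modules, function(m) normals[[m]][1], numeric(1)),
    ny = vapply(topology$modules, function(m) normals[[m]][2], numeric(1)),
    nz = vapply(topology$modules, function(m) normals[[m]][3], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(modules = mods,
                 edges = edges,
                 optodes = optodes[, c("module", "label", "role", "x_mm",
                                       "y_mm", "z_mm", "id")],
                 reference = topology$reference,
                 quaternions = quats),
            class = "shape_estimate")
}

propagate_all_centers <- function(topology, quats, normals) {
  centers <- list()
  centers[[topology$reference]] <- c(0, 0, 0)
  edges <- bfs_tree_edges(topology)
  for (i in seq_len(NROW(edges))) {
    e <- edges[i, ]
    n_r <- normals[[e$from]]; n_p <- normals[[e$to]]
    theta <- normal_angle(n_r, n_p)
    r <- pairwise_radius(theta, e$distance_mm)
    centers[[e$to]] <- propagate_center(
      centers[[e$from]], n_r, n_p, r, l_mm = e$distance_mm,
      tangent = port_tangent(topology$specs[[e$from]], e$port_from,
                             quats[[e$from]]))
  }
  centers
}

edge_radii <- function(topology, normals) {
  w <- topology$wiring
  if (nrow(w) == 0)
    return(data.frame(a = character(), b = character(), theta_rad = numeric(),
                      r_mm = numeric(), flat = logical(),
                      stringsAsFactors = FALSE))
  theta <- vapply(seq_len(nrow(w)), function(i)
    normal_angle(normals[[w$a[i]]], normals[[w$b[i]]]), numeric(1))
  r <- vapply(seq_len(nrow(w)), function(i)
    pairwise_radius(theta[i], w$distance_mm[i]), numeric(1))
  data.frame(a = w$a, b = w$b, theta_rad = theta, r_mm = r,
             flat = is.infinite(r), stringsAsFactors = FALSE)
}

# Mean of the finite incident pairwise radii; Inf if all incident edges are
# flat; NA for an isolated module.
local_radius <- function(edges, module) {
  inc <- edges$r_mm[edges$a == module | edges$b == module]
  if (length(inc) == 0) return(NA_real_)
  fin <- inc[is.finite(inc)]
  if (length(fin) == 0) return(Inf)
  mean(fin)
}

#' Place a module's optodes on its local sphere
#'
#' Each optode's 2D offset \code{(x, y)} from the module center defines an
#' arc length \code{d = sqrt(x^2+y^2)} walked along the geodesic of the
#' local sphere in the tangent direction \code{(x, y)/d} rotated into the
#' world:
#' \code{p = center + r ((cos(d/r) - 1) n + sin(d/r) t)}. In the flat limit
#' the optode is placed at the rotated in-plane offset.
#'
#' @param center module center (mm 3-vector).
#' @param q module orientation quaternion.
#' @param spec the module's [module_spec()].
#' @param r_local local sphere radius in mm (\code{Inf} or \code{NA} = flat).
#' @param normal module normal; recomputed from \code{q} when omitted (the
#'   planar constraint may have adjusted it away from the quaternion's).
#' @param warn_isolated warn that flat placement was used for an isolated
#'   module.
#' @return data frame \code{label}, \code{role}, \code{x_mm}, \code{y_mm},
#'   \code{z_mm}.
#' @export
project_optodes <- function(center, q, spec, r_local, normal = NULL,
                            warn_isolated = FALSE) {
  q <- quat_check(q)
  if (is.null(normal)) normal <- quat_rotate(q, c(0, 0, 1))
  if (warn_isolated)
    warning("module has no incident pairwise radius; using flat placement")
  xy <- module_optode_xy(spec)
  pos <- matrix(NA_real_, nrow(xy), 3)
  flat <- !is.finite(r_local) || is.na(r_local)
  for (i in seq_len(nrow(xy))) {
    v <- c(xy$x_mm[i], xy$y_mm[i])
    d <- sqrt(sum(v^2))
    if (d < 1e-12) {
      pos[i, ] <- center
    } else if (flat) {
      pos[i, ] <- center + quat_rotate(q, c(v, 0))
    } else {
      t_hat <- quat_rotate(q, c(v / d, 0))
      # keep the tangent orthogonal to the (possibly adjusted) normal
      t_hat <- unit3(t_hat - sum(t_hat * normal) * normal)
      pos[i, ] <- center + r_local * ((cos(d / r_local) - 1) * normal +
                                        sin(d / r_local) * t_hat)
    }
  }
  data.frame(label = xy$label, role = xy$role,
             x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Compare estimated and digitized optode positions
#'
#' Registers the estimate to the digitized point set and reports per-optode
#' Euclidean errors. \code{"reference"} mode (the hardware protocol)
#' translates the estimate so the reference module's optode centroid matches
#' its digitized counterpart — module orientations are world-referenced, so
#' only the translation is unknown. \code{"lsq"} mode fits the full rigid
#' transform (Kabsch).
#'
#' @param estimate a [estimate_probe_shape()] result.
#' @param digitized data frame with columns \code{id} (\code{module:label})
#'   and \code{x_mm}, \code{y_mm}, \code{z_mm}; extra optodes are ignored,
#'   missing ones are an error.
#' @param mode \code{"reference"} (default) or \code{"lsq"}.
#' @return object of class \code{"position_comparison"}: \code{per_optode}
#'   (data frame with \code{error_mm}), \code{mean_error_mm},
#'   \code{per_module} (mean error per module), \code{mode}.
#' @export
compare_positions <- function(estimate, digitized,
                              mode = c("reference", "lsq")) {
  mode <- match.arg(mode)
  stopifnot(inherits(estimate, "shape_estimate"))
  if (!all(c("id", "x_mm", "y_mm", "z_mm") %in% names(digitized)))
    stop("digitized positions need columns id, x_mm, y_mm, z_mm")
  est <- estimate$optodes
  idx <- match(est$id, digitized$id)
  if (anyNA(idx))
    stop("digitized positions missing optode(s): ",
         paste(est$id[is.na(idx)], collapse = ", "))
  p_est <- as.matrix(est[, c("x_mm", "y_mm", "z_mm")])
  p_dig <- as.matrix(digitized[idx, c("x_mm", "y_mm", "z_mm")])
  if (mode == "reference") {
    ref <- est$module == estimate$reference
    shift <- colMeans(p_dig[ref, , drop = FALSE]) -
      colMeans(p_est[ref, , drop = FALSE])
    p_reg <- sweep(p_est, 2, shift, `+`)
  } else {
    fit <- kabsch(p_est, p_dig)
    p_reg <- sweep(p_est %*% t(fit$rotation), 2, fit$translation, `+`)
  }
  err <- sqrt(rowSums((p_reg - p_dig)^2))
  per <- data.frame(id = est$id, module = est$module, label = est$label,
                    error_mm = err, stringsAsFactors = FALSE)
  per_module <- tapply(err, est$module, mean)
  structure(list(per_optode = per,
                 mean_error_mm = mean(err),
                 per_module = per_module[order(names(per_module))],
                 mode = mode),
            class = "position_comparison")
}

# Least-squares rigid fit (rotation + translation) mapping x onto y.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  h <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.numeric(cy - rot %*% cx))
}

#' Sphere center from equatorial landmarks
#'
#' Landmarks digitized along the bottom circumference of a hemisphere lie on
#' a circle in the equatorial plane whose center is the sphere center: fit
#' the landmark plane, then the least-squares circle within it.
#'
#' @param landmarks matrix or data frame of >= 3 non-collinear 3D points
#'   (mm).
#' @param radius_mm optional known sphere radius; returned alongside the fit
#'   for comparison with the fitted circle radius.
#' @return list with \code{center} (mm 3-vector), \code{circle_radius_mm},
#'   and \code{radius_mm} as supplied.
#' @export
fit_sphere_center <- function(landmarks, radius_mm = NULL) {
  p <- as.matrix(landmarks)
  if (ncol(p) != 3 || nrow(p) < 3) stop("need >= 3 landmarks in 3D")
  centroid <- colMeans(p)
  q <- sweep(p, 2, centroid)
  sv <- svd(q)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("landmarks are collinear; cannot fit a circle")
  basis <- sv$v[, 1:2]                       # in-plane basis
  uv <- q %*% basis
  # Kasa fit: u^2 + v^2 + D u + E v + F = 0
  a_mat <- cbind(uv, 1)
  rhs <- -rowSums(uv^2)
  coef <- stats::lm.fit(a_mat, rhs)$coefficients
  cuv <- -coef[1:2] / 2
  circle_r <- sqrt(sum(cuv^2) - coef[3])
  center <- centroid + as.numeric(basis %*% cuv)
  list(center = center, circle_radius_mm = as.numeric(circle_r),
       radius_mm = radius_mm)
}

#' Conformity of optode positions to a sphere
#'
#' Distance of each optode to the sphere center, compared with the expected
#' radial distance (surface radius plus module thickness for a perfectly
#' conforming probe).
#'
#' @param positions matrix or data frame of optode positions (mm, columns
#'   x/y/z), or a [estimate_probe_shape()] result.
#' @param center sphere center (mm 3-vector).
#' @param expected_mm expected radial distance in mm.
#' @param tol_mm deviation counted as exceeding (default 5).
#' @param breaks histogram breaks passed to [graphics::hist()] semantics via
#'   [base::cut()]; default bins of 2 mm around the expected distance.
#' @return list with \code{distance_mm}, \code{mean_mm}, \code{sd_mm},
#'   \code{n_exceed} (\code{|d - expected| > tol}), \code{expected_mm},
#'   \code{histogram} (counts per bin).
#' @export
conformity_stats <- function(positions, center, expected_mm, tol_mm = 5,
                             breaks = NULL) {
  if (inherits(positions, "shape_estimate"))
    positions <- positions$optodes[, c("x_mm", "y_mm", "z_mm")]
  p <- as.matrix(as.data.frame(positions)[, 1:3])
  d <- sqrt(rowSums(sweep(p, 2, as.numeric(center))^2))
  if (is.null(breaks)) {
    span <- max(abs(d - expected_mm), tol_mm) + 1
    breaks <- seq(expected_mm - span, expected_mm + span, by = 2)
  }
  h <- table(cut(d, breaks = breaks, include.lowest = TRUE))
  list(distance_mm = as.numeric(d),
       mean_mm = mean(d),
       sd_mm = if (length(d) > 1) stats::sd(d) else 0,
       n_exceed = sum(abs(d - expected_mm) > tol_mm),
       expected_mm = expected_mm,
       tol_mm = tol_mm,
       histogram = h)
}

#' @export
print.shape_estimate <- function(x, ...) {
  cat(sprintf(
    "<shape_estimate> %d modules, %d optodes, reference '%s' at origin\n",
    nrow(x$modules), nrow(x$optodes), x$reference))
  invisible(x)
}

#' @export
print.position_comparison <- function(x, ...) {
  cat(sprintf("<position_comparison> mean error %.2f mm over %d optodes (%s registration)\n",
              x$mean_error_mm, nrow(x$per_optode), x$mode))
  invisible(x)
}
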