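test_that("normal_from_quaternion applies the rotation to (0,0,1)", {
  expect_equal(normal_from_quaternion(c(1, 0, 0, 0)), c(0, 0, 1))
  q90x <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  expect_equal(normal_from_quaternion(q90x), c(0, -1, 0), tolerance = 1e-12)
  q180x <- quat_from_axis_angle(c(1, 0, 0), pi)
  expect_equal(normal_from_quaternion(q180x), c(0, 0, -1), tolerance = 1e-12)
  expect_warning(normal_from_quaternion(c(2, 0, 0, 0)), "normalizing")
})

test_that("rotation_angle is the geodesic angle and handles double cover", {
  q <- quat_from_axis_angle(c(0, 1, 0), 0.8)
  expect_equal(rotation_angle(q, q), 0)
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))) {
    q30 <- quat_from_axis_angle(axis, pi / 6)
    expect_equal(rotation_angle(c(1, 0, 0, 0), q30), pi / 6,
                 tolerance = 1e-12)
  }
  expect_equal(rotation_angle(q, -q), 0, tolerance = 1e-12)
})

test_that("pairwise_radius follows r = L/theta with a flat flag", {
  expect_equal(pairwise_radius(0.5, 55), 110)
  expect_equal(pairwise_radius(pi / 6, 55), 55 * 6 / pi, tolerance = 1e-12)
  expect_equal(pairwise_radius(pi / 6, 55), 105.04, tolerance = 1e-4)
  expect_identical(pairwise_radius(0, 55), Inf)
  expect_identical(pairwise_radius(5e-5, 55), Inf)
  expect_error(pairwise_radius(-0.1, 55))
  expect_error(pairwise_radius(0.5, -1))
})

test_that("propagate_center matches the exact point on the local sphere", {
  p_p <- propagate_center(c(0, 0, 0), c(0, 0, 1),
                          c(sin(0.5), 0, cos(0.5)), 110)
  # independent construction: sphere of radius 110 centered at (0,0,-110),
  # arc length 55 from the north pole
  exact <- c(110 * sin(0.5), 0, 110 * cos(0.5) - 110)
  expect_equal(p_p, exact, tolerance = 1e-12)
  expect_equal(p_p, c(52.74, 0, -13.46), tolerance = 1e-3)
  # degenerate raw application with equal normals collapses onto p_R
  expect_equal(propagate_center(c(1, 2, 3), c(0, 0, 1), c(0, 0, 1), 50),
               c(1, 2, 3))
  # flat branch walks the tangent
  expect_equal(propagate_center(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1), Inf,
                                l_mm = 55, tangent = c(1, 0, 0)),
               c(55, 0, 0))
  # r = 0 keeps the center in place
  expect_equal(propagate_center(c(1, 1, 1), c(0, 0, 1), c(1, 0, 0), 0),
               c(1, 1, 1))
})

test_that("project_optodes places optodes on the local sphere", {
  spec <- module_spec(optodes = list(optode("S3", "source", 0, 19)))
  q <- c(1, 0, 0, 0)
  # module-center optode stays at the center
  ctr_spec <- module_spec(optodes = list(optode("S", "source", 0, 0)))
  p <- project_optodes(c(3, 4, 5), q, ctr_spec, 100)
  expect_equal(as.numeric(p[1, c("x_mm", "y_mm", "z_mm")]), c(3, 4, 5))
  # flat module: rotated in-plane offset
  pf <- project_optodes(c(0, 0, 0), q, spec, Inf)
  expect_equal(as.numeric(pf[1, c("x_mm", "y_mm", "z_mm")]), c(0, 19, 0))
  # curved: chord length from the center is 2 r sin(d / (2r)), on the sphere
  pc <- project_optodes(c(0, 0, 0), q, spec, 100)
  xyz <- as.numeric(pc[1, c("x_mm", "y_mm", "z_mm")])
  expect_equal(sqrt(sum(xyz^2)), 2 * 100 * sin(19 / 200), tolerance = 1e-9)
  expect_equal(sqrt(sum((xyz - c(0, 0, -100))^2)), 100, tolerance = 1e-9)
  expect_warning(project_optodes(c(0, 0, 0), q, spec, NA,
                                 warn_isolated = TRUE), "flat")
})

test_that("noiseless sphere placements are recovered exactly", {
  for (R in c(80, 100, 150)) {
    topo <- v_probe_topology()
    pl <- place_on_surface(topo, surface_sphere(R))
    est <- estimate_probe_shape(topo, add_orientation_noise(pl, 0))
    # per-edge radii all equal R
    expect_equal(est$edges$r_mm, rep(R, nrow(est$edges)), tolerance = 1e-9)
    # centers match ground truth after aligning the reference
    truth_c <- as.matrix(pl$modules[, c("cx_mm", "cy_mm", "cz_mm")])
    ref_c <- truth_c[pl$modules$module == topo$reference, ]
    est_c <- as.matrix(est$modules[, c("cx_mm", "cy_mm", "cz_mm")])
    expect_lt(max(abs(sweep(est_c, 2, -ref_c) - truth_c)), 1e-6)
    # optode positions recovered
    cmp <- compare_positions(est, pl$optodes)
    expect_lt(cmp$mean_error_mm, 0.5)
    expect_lt(max(cmp$per_optode$error_mm), 0.5)
  }
})

test_that("single and flat probes reduce to the planar fold-out", {
  topo <- v_probe_topology()
  pl <- place_on_surface(topo, surface_plane())
  est <- estimate_probe_shape(topo, add_orientation_noise(pl, 0))
  lay <- fold_out_2d(topo)
  expect_equal(est$modules$cx_mm, lay$x_mm, tolerance = 1e-9)
  expect_equal(est$modules$cy_mm, lay$y_mm, tolerance = 1e-9)
  expect_equal(est$modules$cz_mm, rep(0, 5), tolerance = 1e-9)

  solo <- discover_topology(modules = "1")
  q <- quat_from_axis_angle(c(0, 0, 1), 0.3)
  expect_warning(est1 <- estimate_probe_shape(solo, list("1" = q)),
                 "flat placement")
  expect_equal(as.numeric(est1$modules[1, c("cx_mm", "cy_mm", "cz_mm")]),
               c(0, 0, 0))
  flat <- project_optodes(c(0, 0, 0), q, solo$specs[["1"]], NA_real_)
  expect_equal(est1$optodes$x_mm, flat$x_mm)
  expect_equal(est1$optodes$y_mm, flat$y_mm)
})

test_that("flat-limit: estimates converge to the fold-out as R grows", {
  topo <- v_probe_topology()
  lay <- fold_out_2d(topo)
  sup <- vapply(c(1e4, 1e5), function(R) {
    pl <- place_on_surface(topo, surface_sphere(R))
    est <- estimate_probe_shape(topo, add_orientation_noise(pl, 0))
    max(abs(cbind(est$modules$cx_mm - lay$x_mm,
                  est$modules$cy_mm - lay$y_mm,
                  est$modules$cz_mm)))
  }, numeric(1))
  expect_lt(sup[2], sup[1])
  expect_lt(sup[2], 0.1)
})

test_that("estimation is equivariant under a global rotation", {
  topo <- v_probe_topology()
  pl <- place_on_surface(topo, surface_sphere(100))
  imu <- add_orientation_noise(pl, 0)
  g <- quat_from_axis_angle(c(1, 2, 3), 0.7)
  imu_rot <- imu
  for (i in seq_len(nrow(imu))) {
    q <- as.numeric(imu[i, c("qw", "qx", "qy", "qz")])
    imu_rot[i, c("qw", "qx", "qy", "qz")] <- quat_multiply(g, q)
  }
  est <- estimate_probe_shape(topo, imu)
  est_rot <- estimate_probe_shape(topo, imu_rot)
  rotm <- quat_to_matrix(g)
  p <- as.matrix(est$optodes[, c("x_mm", "y_mm", "z_mm")])
  p_rot <- as.matrix(est_rot$optodes[, c("x_mm", "y_mm", "z_mm")])
  expect_equal(unname(p_rot), unname(p %*% t(rotm)), tolerance = 1e-9)
})

test_that("planar constraint projects perturbed normals into the chain
           plane and leaves coplanar chains untouched", {
  topo <- chain_topology(3)
  pl <- place_on_surface(topo, surface_sphere(100))
  normals <- lapply(pl$quaternions, function(q) quat_rotate(q, c(0, 0, 1)))
  adjusted <- apply_planar_constraint(topo, normals)
  for (m in names(normals))
    expect_equal(adjusted[[m]], normals[[m]], tolerance = 1e-12)

  # perturb the end module's normal 2 degrees out of the chain plane
  plane_n <- unit3(cross3(normals[["1"]], normals[["3"]]))
  tilt <- quat_from_axis_angle(cross3(plane_n, normals[["3"]]),
                               2 * pi / 180)
  normals[["3"]] <- quat_rotate(tilt, normals[["3"]])
  expect_gt(abs(sum(normals[["3"]] * plane_n)), 1e-3)  # out of plane now
  adjusted <- apply_planar_constraint(topo, normals)
  # all adjusted normals lie in a common plane (the averaged one)
  m_avg <- unit3(cross3(adjusted[["1"]], adjusted[["2"]]))
  for (m in c("1", "2", "3")) {
    expect_unit(adjusted[[m]])
    expect_lt(abs(sum(adjusted[[m]] * m_avg)), 1e-9)
  }
  # in-plane component of the perturbed normal is preserved in direction
  n3_inplane <- unit3(normals[["3"]] -
                        sum(normals[["3"]] * m_avg) * m_avg)
  expect_equal(adjusted[["3"]], n3_inplane, tolerance = 1e-9)

  # 2-module chains are a no-op
  two <- chain_topology(2)
  n2 <- list("1" = c(0, 0, 1), "2" = unit3(c(0.1, 0.2, 1)))
  expect_equal(apply_planar_constraint(two, n2), n2)
})

test_that("orientation noise degrades accuracy gracefully and monotonically", {
  topo <- v_probe_topology()
  pl <- place_on_surface(topo, surface_sphere(100))
  mean_err <- vapply(c(0.5, 1, 2, 4), function(sg) {
    mean(vapply(1:50, function(s) {
      imu <- add_orientation_noise(pl, sg, seed = s)
      compare_positions(estimate_probe_shape(topo, imu),
                        pl$optodes)$mean_error_mm
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
  expect_true(all(is.finite(mean_err)))
})

test_that("compare_positions is a metric identity and lsq removes rigid
           offsets", {
  topo <- v_probe_topology()
  pl <- place_on_surface(topo, surface_sphere(100))
  est <- estimate_probe_shape(topo, add_orientation_noise(pl, 0))
  self <- est$optodes[, c("id", "x_mm", "y_mm", "z_mm")]
  cmp <- compare_positions(est, self)
  expect_equal(cmp$mean_error_mm, 0, tolerance = 1e-12)
  expect_true(all(cmp$per_optode$error_mm >= 0))
  expect_equal(cmp$mean_error_mm, mean(cmp$per_optode$error_mm))

  shifted <- self
  shifted$x_mm <- shifted$x_mm + 3
  cmp_lsq <- compare_positions(est, shifted, mode = "lsq")
  expect_equal(cmp_lsq$mean_error_mm, 0, tolerance = 1e-9)
  # per-module means average the per-optode errors
  cmp2 <- compare_positions(est, pl$optodes)
  agg <- tapply(cmp2$per_optode$error_mm, cmp2$per_optode$module, mean)
  expect_equal(as.numeric(cmp2$per_module),
               as.numeric(agg[names(cmp2$per_module)]))
  expect_error(compare_positions(est, self[-1, ]), "missing")
})

test_that("fit_sphere_center recovers the center from equatorial landmarks", {
  lm <- rbind(c(100, 0, 0), c(-100, 0, 0), c(0, 100, 0), c(0, -100, 0))
  fit <- fit_sphere_center(lm, 100)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$circle_radius_mm, 100, tolerance = 1e-9)
  fit2 <- fit_sphere_center(sweep(lm, 2, c(-5, -5, 0)), 100)
  expect_equal(fit2$center, c(5, 5, 0), tolerance = 1e-9)
  expect_error(fit_sphere_center(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
  # noisy landmarks: center recovered to ~1 mm on average over replicates
  set.seed(42)
  angles <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(100 * cos(angles), 100 * sin(angles), 0)
  errs <- replicate(100, {
    noisy <- ring + matrix(rnorm(length(ring), 0, 1), ncol = 3)
    sqrt(sum(fit_sphere_center(noisy)$center^2))
  })
  expect_lt(mean(errs), 1.5)
})

test_that("conformity statistics flag departures from the expected radius", {
  angles <- seq(0.1, 1.2, length.out = 25)
  pts <- cbind(105 * sin(angles), 0, 105 * cos(angles))
  st <- conformity_stats(pts, c(0, 0, 0), expected_mm = 105)
  expect_equal(st$mean_mm, 105, tolerance = 1e-9)
  expect_equal(st$sd_mm, 0, tolerance = 1e-9)
  expect_equal(st$n_exceed, 0)

  alt <- ifelse(seq_len(24) %% 2 == 0, 110, 100)
  pts2 <- cbind(alt, 0, 0)
  st2 <- conformity_stats(pts2, c(0, 0, 0), expected_mm = 105, tol_mm = 4)
  expect_equal(st2$mean_mm, 105)
  expect_equal(st2$sd_mm, sd(alt))
  expect_equal(st2$n_exceed, 24)  # both 100 and 110 deviate by 5 > 4

  st3 <- conformity_stats(rbind(c(111, 0, 0)), c(0, 0, 0), 105)
  expect_equal(st3$n_exceed, 1)
})

test_that("shape estimation completes well under a second", {
  topo <- chain_topology(20)
  pl <- place_on_surface(topo, surface_sphere(300))
  imu <- add_orientation_noise(pl, 0)
  elapsed <- system.time(estimate_probe_shape(topo, imu))[["elapsed"]]
  expect_lt(elapsed, 1)
})

test_that("missing quaternions and disconnected probes are rejected", {
  topo <- v_probe_topology()
  pl <- place_on_surface(topo, surface_sphere(100))
  imu <- add_orientation_noise(pl, 0)
  expect_error(estimate_probe_shape(topo, imu[-1, ]), "missing IMU")
})
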