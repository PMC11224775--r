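# Programmatic fixtures: probe topologies used across the suite.

chain_topology <- function(n, distance_mm = 55) {
  ids <- as.character(seq_len(n))
  discover_topology(wiring_list(
    a = ids[-n], port_a = rep(1L, n - 1),
    b = ids[-1], port_b = rep(3L, n - 1),
    distance_mm = distance_mm))
}

star_topology <- function(distance_mm = 55) {
  # one hub wired on all four ports: the most tightly packed 5-module probe
  discover_topology(wiring_list(
    a = rep("1", 4), port_a = 1:4,
    b = as.character(2:5), port_b = c(3L, 4L, 1L, 2L),
    distance_mm = distance_mm))
}

# Random connected probe grown as a tree on free ports; deterministic per
# seed. Degree <= 4 and one-use-per-port hold by construction.
random_topology <- function(seed, n_min = 3, n_max = 8, distance_mm = 55) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  ids <- as.character(seq_len(n))
  free <- stats::setNames(lapply(ids, function(i) 1:4), ids)
  a <- pa <- b <- pb <- NULL
  resample <- function(x) x[sample.int(length(x), 1)]
  for (i in 2:n) {
    open <- names(free)[vapply(free, length, integer(1)) > 0 &
                          names(free) < ids[i]]
    parent <- resample(open)
    pa_i <- resample(free[[parent]])
    pb_i <- resample(1:4)
    free[[parent]] <- setdiff(free[[parent]], pa_i)
    free[[ids[i]]] <- setdiff(free[[ids[i]]], pb_i)
    a <- c(a, parent); pa <- c(pa, pa_i)
    b <- c(b, ids[i]); pb <- c(pb, pb_i)
  }
  discover_topology(wiring_list(a = a, port_a = pa, b = b, port_b = pb,
                                distance_mm = distance_mm))
}

expect_unit <- function(v, tol = 1e-9) {
  expect_equal(sqrt(sum(v^2)), 1, tolerance = tol)
}
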