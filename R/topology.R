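# Probe connection topology: which module ports are wired to which, and the
# deterministic 2D fold-out used for multiplexing-group assignment.

#' Construct a wiring list
#'
#' Each entry records one inter-module cable: module \code{a}'s port
#' \code{port_a} wired to module \code{b}'s port \code{port_b}, with the
#' center-to-center distance the cable enforces (55 mm for the standard
#' short cables).
#'
#' @param a,b character module ids.
#' @param port_a,port_b port indices 1..4.
#' @param distance_mm center-to-center distance(s) in mm, recycled.
#' @return data frame of class \code{"wiring_list"}.
#' @export
wiring_list <- function(a = character(), port_a = integer(),
                        b = character(), port_b = integer(),
                        distance_mm = 55) {
  w <- data.frame(a = as.character(a), port_a = as.integer(port_a),
                  b = as.character(b), port_b = as.integer(port_b),
                  distance_mm = as.numeric(rep_len(distance_mm,
                                                   length.out = length(a))),
                  stringsAsFactors = FALSE)
  class(w) <- c("wiring_list", "data.frame")
  w
}

#' Build a probe topology from a wiring list
#'
#' Mirrors the computer-side half of automatic connection-topology
#' recognition: given which ports are wired together, construct the probe
#' graph, validate it (no port used twice, at most four neighbors per module,
#' a single connected probe), and pick a reference module.
#'
#' @param wiring a [wiring_list()] (or data frame with the same columns).
#' @param modules character module ids; defaults to the ids present in the
#'   wiring. Must be supplied for a single unwired module.
#' @param specs a single [module_spec()] shared by all modules, or a named
#'   list of specs keyed by module id. Defaults to [default_module_layout()].
#' @param reference reference module id; defaults to a graph center (a module
#'   of minimum eccentricity, smallest id on ties).
#' @return an object of class \code{"probe_topology"} with fields
#'   \code{modules}, \code{specs}, \code{wiring}, \code{reference},
#'   \code{graph} (an igraph).
#' @export
discover_topology <- function(wiring = wiring_list(), modules = NULL,
                              specs = default_module_layout(),
                              reference = NULL) {
  wiring <- as.data.frame(wiring, stringsAsFactors = FALSE)
  needed <- c("a", "port_a", "b", "port_b", "distance_mm")
  if (!all(needed %in% names(wiring)))
    stop("wiring must have columns a, port_a, b, port_b, distance_mm")
  if (is.null(modules)) modules <- union(wiring$a, wiring$b)
  modules <- sort(unique(as.character(modules)))
  if (length(modules) == 0) stop("probe has no modules")
  if (!all(c(wiring$a, wiring$b) %in% modules))
    stop("wiring references undeclared modules")
  if (any(wiring$distance_mm <= 0))
    stop("center distances must be positive")
  if (any(wiring$a == wiring$b))
    stop("a module cannot be wired to itself")
  if (any(!wiring$port_a %in% 1:4) || any(!wiring$port_b %in% 1:4))
    stop("port indices must be in 1..4")
  ends <- c(paste(wiring$a, wiring$port_a, sep = ":"),
            paste(wiring$b, wiring$port_b, sep = ":"))
  if (anyDuplicated(ends))
    stop("duplicate port use: ", paste(ends[duplicated(ends)], collapse = ", "))
  deg <- table(c(wiring$a, wiring$b))
  if (any(deg > 4))
    stop("module degree exceeds 4: ",
         paste(names(deg)[deg > 4], collapse = ", "))
  g <- igraph::graph_from_data_frame(
    if (nrow(wiring)) wiring[, c("a", "b")] else
      data.frame(a = character(), b = character()),
    directed = FALSE,
    vertices = data.frame(name = modules, stringsAsFactors = FALSE))
  if (!igraph::is_connected(g) && length(modules) > 1)
    stop("probe graph is disconnected")
  if (is.list(specs) && !inherits(specs, "module_spec")) {
    if (!all(modules %in% names(specs)))
      stop("specs list must be named by module id and cover every module")
    specs <- specs[modules]
  } else {
    stopifnot(inherits(specs, "module_spec"))
    specs <- stats::setNames(rep(list(specs), length(modules)), modules)
  }
  if (is.null(reference)) {
    ecc <- igraph::eccentricity(g)
    reference <- sort(names(ecc)[ecc == min(ecc)])[1]
  } else {
    reference <- as.character(reference)
    if (!reference %in% modules) stop("reference module not in probe")
  }
  structure(list(modules = modules, specs = specs,
                 wiring = wiring[, needed], reference = reference,
                 graph = g),
            class = "probe_topology")
}

# Adjacency as a list: for each module, data frame of (neighbor, own port,
# neighbor's port, distance), sorted by neighbor id for deterministic BFS.
topology_adjacency <- function(topology) {
  adj <- stats::setNames(vector("list", length(topology$modules)),
                         topology$modules)
  w <- topology$wiring
  for (i in seq_len(nrow(w))) {
    adj[[w$a[i]]] <- rbind(adj[[w$a[i]]], data.frame(
      to = w$b[i], port_from = w$port_a[i], port_to = w$port_b[i],
      distance_mm = w$distance_mm[i], stringsAsFactors = FALSE))
    adj[[w$b[i]]] <- rbind(adj[[w$b[i]]], data.frame(
      to = w$a[i], port_from = w$port_b[i], port_to = w$port_a[i],
      distance_mm = w$distance_mm[i], stringsAsFactors = FALSE))
  }
  lapply(adj, function(d) if (is.null(d)) d else d[order(d$to), , drop = FALSE])
}

# Breadth-first tree edges from the reference, neighbors visited in
# ascending module id. Returns a data frame of directed tree edges.
bfs_tree_edges <- function(topology) {
  adj <- topology_adjacency(topology)
  visited <- topology$reference
  queue <- topology$reference
  edges <- NULL
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- adj[[cur]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      if (nb$to[i] %in% visited) next
      visited <- c(visited, nb$to[i])
      queue <- c(queue, nb$to[i])
      edges <- rbind(edges, data.frame(
        from = cur, to = nb$to[i], port_from = nb$port_from[i],
        port_to = nb$port_to[i], distance_mm = nb$distance_mm[i],
        stringsAsFactors = FALSE))
    }
  }
  edges
}

#' Fold a probe topology out into the plane
#'
#' Deterministic breadth-first placement from the reference module: each
#' unplaced neighbor is put at the edge's center distance along the world
#' direction of the connecting port, and rotated so that its own connecting
#' port points straight back. Traversal visits neighbors in ascending module
#' id, so the layout is reproducible.
#'
#' @param topology a [discover_topology()] result.
#' @return data frame of class \code{"planar_layout"} with columns
#'   \code{module}, \code{x_mm}, \code{y_mm}, \code{rotation_rad}; the
#'   topology is attached as attribute \code{"topology"}.
#' @export
fold_out_2d <- function(topology) {
  stopifnot(inherits(topology, "probe_topology"))
  pose <- list()
  pose[[topology$reference]] <- c(x = 0, y = 0, rot = 0)
  edges <- bfs_tree_edges(topology)
  rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  for (i in seq_len(NROW(edges))) {
    e <- edges[i, ]
    from_pose <- pose[[e$from]]
    spec_from <- topology$specs[[e$from]]
    spec_to <- topology$specs[[e$to]]
    dir_local <- spec_from$ports[[e$port_from]]$outward_dir
    dir_world <- as.numeric(rot2(from_pose["rot"]) %*% dir_local)
    center <- unname(c(from_pose["x"], from_pose["y"])) +
      e$distance_mm * dir_world
    back_local <- spec_to$ports[[e$port_to]]$outward_dir
    rot_to <- atan2(-dir_world[2], -dir_world[1]) -
      atan2(back_local[2], back_local[1])
    pose[[e$to]] <- c(x = center[1], y = center[2],
                      rot = atan2(sin(rot_to), cos(rot_to)))
  }
  out <- data.frame(
    module = topology$modules,
    x_mm = vapply(topology$modules, function(m) pose[[m]][["x"]], numeric(1)),
    y_mm = vapply(topology$modules, function(m) pose[[m]][["y"]], numeric(1)),
    rotation_rad = vapply(topology$modules, function(m) pose[[m]][["rot"]],
                          numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(out) > 1) {
    d <- as.matrix(stats::dist(out[, c("x_mm", "y_mm")]))
    diag(d) <- Inf
    if (any(d < 1))
      warning("fold-out placed two module centers within 1 mm of each other")
  }
  class(out) <- c("planar_layout", "data.frame")
  attr(out, "topology") <- topology
  out
}

#' Optode world coordinates of a planar layout
#'
#' @param layout a [fold_out_2d()] result.
#' @return data frame with columns \code{module}, \code{label}, \code{role},
#'   \code{x_mm}, \code{y_mm}, \code{z_mm} (zero), and \code{id}
#'   (\code{"module:label"}).
#' @export
layout_optodes <- function(layout) {
  stopifnot(inherits(layout, "planar_layout"))
  topology <- attr(layout, "topology")
  out <- NULL
  for (i in seq_len(nrow(layout))) {
    m <- layout$module[i]
    a <- layout$rotation_rad[i]
    xy <- module_optode_xy(topology$specs[[m]])
    x <- layout$x_mm[i] + cos(a) * xy$x_mm - sin(a) * xy$y_mm
    y <- layout$y_mm[i] + sin(a) * xy$x_mm + cos(a) * xy$y_mm
    out <- rbind(out, data.frame(
      module = m, label = xy$label, role = xy$role,
      x_mm = x, y_mm = y, z_mm = 0,
      id = paste(m, xy$label, sep = ":"), stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.probe_topology <- function(x, ...) {
  cat(sprintf("<probe_topology> %d modules, %d cables, reference '%s'\n",
              length(x$modules), nrow(x$wiring), x$reference))
  invisible(x)
}

#' Summarize a probe topology
#'
#' @param object a [discover_topology()] result.
#' @param ... unused.
#' @return list with module ids, degrees, reference, straight chains.
#' @export
summary.probe_topology <- function(object, ...) {
  deg <- igraph::degree(object$graph)
  list(n_modules = length(object$modules),
       n_edges = nrow(object$wiring),
       degrees = deg[order(names(deg))],
       reference = object$reference,
       chains = straight_chains(object))
}

# Maximal straight chains: paths in which every interior module is entered
# and left through opposite ports (1-3 or 2-4). Used by the planar
# constraint during shape estimation.
straight_chains <- function(topology) {
  adj <- topology_adjacency(topology)
  chains <- list()
  w <- topology$wiring
  for (i in seq_len(nrow(w))) {
    # extend the seed edge in both directions while the pass-through is
    # opposite-port
    chain <- c(w$a[i], w$b[i])
    extend <- function(chain, end_port_in) {
      repeat {
        cur <- chain[length(chain)]
        nb <- adj[[cur]]
        if (is.null(nb)) return(chain)
        out_port <- opposite_port(end_port_in)
        hit <- nb[nb$port_from == out_port & !(nb$to %in% chain), ,
                  drop = FALSE]
        if (nrow(hit) == 0) return(chain)
        chain <- c(chain, hit$to[1])
        end_port_in <- hit$port_to[1]
      }
    }
    chain <- extend(chain, w$port_b[i])
    chain <- rev(extend(rev(chain), w$port_a[i]))
    if (length(chain) >= 3) chains[[length(chains) + 1]] <- chain
  }
  # dedupe (same chain discovered from each of its edges)
  keys <- vapply(chains, function(ch) {
    paste(if (ch[1] < ch[length(ch)]) ch else rev(ch), collapse = ">")
  }, character(1))
  chains[!duplicated(keys)]
}
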