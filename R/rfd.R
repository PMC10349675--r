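# River Formation Dynamics: drops walk a weighted graph toward a goal node of
# fixed altitude 0, choosing moves by downhill gradient, eroding the nodes
# they traverse and redistributing the eroded soil as sediment.  Over
# iterations good routes deepen into "riverbeds".

#' RFD environment: weighted graph with node altitudes
#'
#' Starts flat: every node at `init_altitude` except the goal, which is fixed
#' at 0 for the whole run.
#'
#' @param edges data frame with columns `src`, `dst`, `distance`
#'   (positive); node names are taken from the union of `src` and `dst`.
#' @param goal name of the goal node.
#' @param init_altitude starting altitude of non-goal nodes (default 100).
#' @param directed treat edges as directed? Default FALSE (each edge usable
#'   both ways).
#' @return An object of class `rfd_environment`: node names, adjacency lists
#'   (`adj`, `dist`), `altitude` vector, `goal` index.
#' @export
rfd_environment <- function(edges, goal, init_altitude = 100,
                            directed = FALSE) {
  stopifnot(all(c("src", "dst", "distance") %in% names(edges)))
  if (any(edges$distance <= 0)) stop_field("distance", "must be positive")
  if (!directed) {
    edges <- rbind(edges[, c("src", "dst", "distance")],
                   stats::setNames(edges[, c("dst", "src", "distance")],
                                   c("src", "dst", "distance")))
    edges <- edges[!duplicated(edges[, c("src", "dst")]), ]
  }
  nodes <- sort(unique(c(as.character(edges$src), as.character(edges$dst))))
  if (!goal %in% nodes) stop_field("goal", "not a node of the graph")
  gi <- match(goal, nodes)
  adj <- vector("list", length(nodes))
  dist <- vector("list", length(nodes))
  si <- match(as.character(edges$src), nodes)
  di <- match(as.character(edges$dst), nodes)
  for (n in seq_along(nodes)) {
    sel <- si == n
    adj[[n]] <- di[sel]
    dist[[n]] <- as.numeric(edges$distance[sel])
  }
  altitude <- rep(as.numeric(init_altitude), length(nodes))
  altitude[gi] <- 0
  structure(list(nodes = nodes, adj = adj, dist = dist, altitude = altitude,
                 goal = gi, init_altitude = as.numeric(init_altitude)),
            class = "rfd_environment")
}

#' @export
print.rfd_environment <- function(x, ...) {
  cat(sprintf("rfd_environment: %d nodes, %d directed edges, goal %s\n",
              length(x$nodes), sum(lengths(x$adj)), x$nodes[x$goal]))
  invisible(x)
}

#' Build the n-by-n unit grid environment
#'
#' Nodes are named `r<i>c<j>`; 4-neighbour lattice with unit distances, the
#' standard terminal-routing testbed.
#'
#' @param n side length.
#' @param goal,source node names; defaults put the source at the bottom-left
#'   corner and the goal at the top-right corner.
#' @param init_altitude starting altitude.
#' @return An `rfd_environment` with attribute `source`.
#' @export
grid_environment <- function(n, goal = sprintf("r%dc%d", n, n),
                             source = "r1c1", init_altitude = 100) {
  n <- check_count(n, "n", min = 2L)
  e <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < n) e[[length(e) + 1L]] <- c(sprintf("r%dc%d", i, j),
                                          sprintf("r%dc%d", i, j + 1L))
      if (i < n) e[[length(e) + 1L]] <- c(sprintf("r%dc%d", i, j),
                                          sprintf("r%dc%d", i + 1L, j))
    }
  }
  edges <- data.frame(src = vapply(e, `[`, character(1), 1),
                      dst = vapply(e, `[`, character(1), 2),
                      distance = 1, stringsAsFactors = FALSE)
  env <- rfd_environment(edges, goal = goal, init_altitude = init_altitude)
  attr(env, "source") <- source
  env
}

#' RFD parameters
#'
#' @param omega uphill coefficient: an uphill neighbour with gradient g gets
#'   unnormalised weight `omega / |g|`, so steep climbs are unlikely but
#'   never impossible.
#' @param delta flat coefficient: unnormalised weight of a flat neighbour.
#' @param E erosion coefficient of the per-pair erosion rule.
#' @param n_drops number of drops per iteration (D).
#' @param init_altitude flat starting altitude.
#' @param sediment_fraction share of carried sediment a stopped (dead-end)
#'   drop deposits on its final node before evaporating.
#' @param max_iter,patience iteration cap and no-improvement stop.
#' @param epsilon altitude floor for non-goal nodes, keeping gradients
#'   finite.
#' @return An object of class `rfd_params`.
#' @export
rfd_params <- function(omega = 0.2, delta = 0.1, E = 1, n_drops = 10L,
                       init_altitude = 100, sediment_fraction = 0.5,
                       max_iter = 100L, patience = 25L, epsilon = 1e-6) {
  structure(list(
    omega = check_number(omega, "omega", lower = 0, open_lower = TRUE),
    delta = check_number(delta, "delta", lower = 0, open_lower = TRUE),
    E = check_number(E, "E", lower = 0, open_lower = TRUE),
    n_drops = check_count(n_drops, "n_drops"),
    init_altitude = check_number(init_altitude, "init_altitude", lower = 0,
                                 open_lower = TRUE),
    sediment_fraction = check_number(sediment_fraction, "sediment_fraction",
                                     lower = 0, upper = 1),
    max_iter = check_count(max_iter, "max_iter"),
    patience = check_count(patience, "patience"),
    epsilon = check_number(epsilon, "epsilon", lower = 0, open_lower = TRUE)
  ), class = "rfd_params")
}

#' Gradient between adjacent nodes
#'
#' `(altitude(i) - altitude(j)) / distance(i, j)`: positive means downhill
#' from i to j.
#'
#' @param env an `rfd_environment`.
#' @param i,j node names or indices; the edge (i, j) must exist.
#' @return Numeric gradient.
#' @export
gradient <- function(env, i, j) {
  stopifnot(inherits(env, "rfd_environment"))
  i <- .node_idx(env, i); j <- .node_idx(env, j)
  pos <- match(j, env$adj[[i]])
  if (is.na(pos)) {
    stop(sprintf("no edge from %s to %s", env$nodes[i], env$nodes[j]),
         call. = FALSE)
  }
  (env$altitude[i] - env$altitude[j]) / env$dist[[i]][pos]
}

.node_idx <- function(env, x) {
  if (is.character(x)) {
    ix <- match(x, env$nodes)
    if (is.na(ix)) stop_field("node", paste("unknown node", x))
    ix
  } else {
    as.integer(x)
  }
}

#' Transition probabilities of a drop at node i
#'
#' Neighbours are partitioned by gradient sign into downhill (positive),
#' uphill (negative) and flat sets; unnormalised weights are the gradient,
#' `omega / |gradient|` and `delta` respectively, normalised by their sum.
#'
#' @param env an `rfd_environment`.
#' @param i current node (name or index).
#' @param params an [rfd_params()].
#' @param exclude optional node (name or index) removed from the neighbour
#'   set -- used to forbid immediate backtracking.
#' @return List with `neighbors` (indices), `prob`, `gradients`, `partition`
#'   (factor `down`/`up`/`flat`) and the normaliser `total`.
#' @export
transition_probabilities <- function(env, i, params = rfd_params(),
                                     exclude = NULL) {
  stopifnot(inherits(env, "rfd_environment"))
  i <- .node_idx(env, i)
  nb <- env$adj[[i]]
  dd <- env$dist[[i]]
  if (!is.null(exclude)) {
    ex <- .node_idx(env, exclude)
    keep <- nb != ex
    nb <- nb[keep]; dd <- dd[keep]
  }
  if (!length(nb)) {
    stop(sprintf("node %s has no admissible neighbours", env$nodes[i]),
         call. = FALSE)
  }
  g <- (env$altitude[i] - env$altitude[nb]) / dd
  part <- factor(ifelse(g > 0, "down", ifelse(g < 0, "up", "flat")),
                 levels = c("down", "up", "flat"))
  wt <- numeric(length(g))
  wt[part == "down"] <- g[part == "down"]
  wt[part == "up"] <- params$omega / abs(g[part == "up"])
  wt[part == "flat"] <- params$delta
  total <- sum(wt)
  list(neighbors = nb, prob = wt / total, gradients = g, partition = part,
       total = total)
}

#' Walk one drop from start toward the goal
#'
#' Successive nodes are sampled from [transition_probabilities()] with
#' immediate backtracking forbidden, until the goal is reached or the drop
#' has visited as many nodes as the graph has (the cap the method
#' prescribes).  A drop whose only neighbour is the node it just came from
#' is stuck and stops early.
#'
#' @param env an `rfd_environment`.
#' @param start start node (name or index).
#' @param params an [rfd_params()].
#' @return List of class `drop_path`: `nodes` (index vector), `reached_goal`,
#'   `cost` (sum of traversed distances, `Inf` when the goal was not
#'   reached).
#' @export
move_drop <- function(env, start, params = rfd_params()) {
  stopifnot(inherits(env, "rfd_environment"))
  cur <- .node_idx(env, start)
  n_max <- length(env$nodes)
  path <- integer(n_max)
  path[1] <- cur
  len <- 1L
  prev <- 0L
  cost <- 0
  while (cur != env$goal && len < n_max) {
    nb <- env$adj[[cur]]
    dd <- env$dist[[cur]]
    if (prev != 0L) {
      keep <- nb != prev
      nb <- nb[keep]; dd <- dd[keep]
    }
    if (!length(nb)) break  # dead end: drop is stuck
    g <- (env$altitude[cur] - env$altitude[nb]) / dd
    wt <- ifelse(g > 0, g,
                 ifelse(g < 0, params$omega / abs(g), params$delta))
    nxt_pos <- if (length(nb) == 1L) 1L else {
      sample.int(length(nb), 1L, prob = wt)
    }
    prev <- cur
    cost <- cost + dd[nxt_pos]
    cur <- nb[nxt_pos]
    len <- len + 1L
    path[len] <- cur
  }
  reached <- cur == env$goal
  structure(list(nodes = path[seq_len(len)], reached_goal = reached,
                 cost = if (reached) cost else Inf),
            class = "drop_path")
}

#' Erode the environment along drop paths
#'
#' For every consecutive pair (i, j) of every path, in traversal order,
#' `altitude(i)` loses `E / ((N - 1) * D) * gradient(i, j)` evaluated at the
#' current altitudes (an uphill step, negative gradient, raises the node).
#' The goal's altitude never changes and non-goal altitudes are floored at
#' `epsilon`.  Stopped (non-goal-reaching) drops then dump
#' `sediment_fraction` of the soil they carried onto their final node,
#' raising it and so weakening blind alleys.
#'
#' @param env an `rfd_environment`.
#' @param paths list of `drop_path` objects from the current iteration.
#' @param params an [rfd_params()]; `n_drops` is taken as D.
#' @return List: updated `env`, total signed `erosion_produced`, and
#'   `carried` (per-path eroded soil).
#' @export
erode <- function(env, paths, params = rfd_params()) {
  stopifnot(inherits(env, "rfd_environment"))
  n_nodes <- length(env$nodes)
  coef <- params$E / ((n_nodes - 1) * params$n_drops)
  produced <- 0
  carried <- numeric(length(paths))
  alt <- env$altitude
  for (k in seq_along(paths)) {
    p <- paths[[k]]$nodes
    if (length(p) < 2L) next
    acc <- 0
    for (s in seq_len(length(p) - 1L)) {
      i <- p[s]; j <- p[s + 1L]
      if (i == env$goal) next
      pos <- match(j, env$adj[[i]])
      g <- (alt[i] - alt[j]) / env$dist[[i]][pos]
      new_alt <- max(params$epsilon, alt[i] - coef * g)
      acc <- acc + (alt[i] - new_alt)
      alt[i] <- new_alt
    }
    produced <- produced + acc
    carried[k] <- acc
    if (!paths[[k]]$reached_goal && params$sediment_fraction > 0 && acc > 0) {
      last <- p[length(p)]
      if (last != env$goal) {
        alt[last] <- alt[last] + params$sediment_fraction * acc
      }
    }
  }
  env$altitude <- alt
  list(env = env, erosion_produced = produced, carried = carried)
}

#' Deposit sediment across all non-goal nodes
#'
#' Adds `erosion_produced / (N - 1)` to every non-goal node, so the soil
#' removed in an iteration is conserved and altitudes never collapse to a
#' gradient-free flat.
#'
#' @param env an `rfd_environment`.
#' @param erosion_produced non-negative total from [erode()].
#' @return Updated environment.
#' @export
deposit_sediment <- function(env, erosion_produced) {
  stopifnot(inherits(env, "rfd_environment"))
  if (erosion_produced < 0) {
    stop_field("erosion_produced", "must be non-negative")
  }
  inc <- erosion_produced / (length(env$nodes) - 1)
  env$altitude <- env$altitude + inc
  env$altitude[env$goal] <- 0
  env
}

#' Run River Formation Dynamics
#'
#' Iterates move-all-drops, erode, stopped-drop sediment dumps and global
#' sediment deposit until `max_iter` iterations or `patience` iterations
#' without improvement of the best goal-reaching path cost.
#'
#' @param env a flat-initialised `rfd_environment`.
#' @param start start node; defaults to the environment's `source` attribute.
#' @param params an [rfd_params()].
#' @param seed integer seed (NULL uses the current RNG state).
#' @return List of class `rfd_result`: `best_path` (node names, or NULL when
#'   no drop ever reached the goal), `best_cost`, `reached_goal`,
#'   `iterations`, final `env`, `history` (best cost per iteration).
#' @export
run_rfd <- function(env, start = attr(env, "source"), params = rfd_params(),
                    seed = NULL) {
  stopifnot(inherits(env, "rfd_environment"))
  if (is.null(start)) stop_field("start", "no start node given")
  with_seed(seed, {
    best_cost <- Inf
    best_path <- NULL
    history <- numeric(0)
    stale <- 0L
    it <- 0L
    while (it < params$max_iter) {
      it <- it + 1L
      paths <- lapply(seq_len(params$n_drops), function(k) {
        move_drop(env, start, params)
      })
      improved <- FALSE
      for (p in paths) {
        if (p$reached_goal && p$cost < best_cost) {
          best_cost <- p$cost
          best_path <- env$nodes[p$nodes]
          improved <- TRUE
        }
      }
      er <- erode(env, paths, params)
      env <- deposit_sediment(er$env, max(0, er$erosion_produced))
      history <- c(history, best_cost)
      stale <- if (improved) 0L else stale + 1L
      if (stale >= params$patience && is.finite(best_cost)) break
    }
    structure(list(best_path = best_path, best_cost = best_cost,
                   reached_goal = !is.null(best_path), iterations = it,
                   env = env, history = history),
              class = "rfd_result")
  })
}

#' @export
print.rfd_result <- function(x, ...) {
  if (x$reached_goal) {
    cat(sprintf("rfd_result: best cost %.4g over %d iterations (path %d nodes)\n",
                x$best_cost, x$iterations, length(x$best_path)))
  } else {
    cat(sprintf("rfd_result: no drop reached the goal in %d iterations\n",
                x$iterations))
  }
  invisible(x)
}
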