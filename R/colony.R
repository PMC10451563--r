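#' Control parameters of the ant-colony search
#'
#' Tunable parameters of one ant colony. Defaults are the settings that the
#' search was calibrated with: pheromone exponent `alpha = 1.2`, heuristic
#' exponent `beta = 2`, evaporation `rho = 0.35`, exploitation threshold
#' `q0 = 0.75`, `ants = 20` constructions per iteration and `iterations = 10`.
#' `tau0` is the initial pheromone level on every arc and `lstep` caps the
#' hill-climbing sweeps of the local search.
#'
#' @param alpha pheromone exponent of the exploration rule (`> 0`).
#' @param beta heuristic exponent (`> 0`).
#' @param rho pheromone evaporation rate, in `(0, 1]`.
#' @param q0 exploitation probability, in `[0, 1)`: with probability `q0` an
#'   ant takes the arc maximizing `tau * eta^beta`; otherwise it samples an
#'   arc with probability proportional to `tau^alpha * eta^beta`.
#' @param tau0 initial pheromone level (`> 0`).
#' @param ants number of ants (graph constructions) per iteration.
#' @param iterations number of colony iterations.
#' @param lstep maximum local-search sweeps per iteration.
#' @return list of class `"acnet_control"`.
#' @export
acnet_control <- function(alpha = 1.2, beta = 2, rho = 0.35, q0 = 0.75,
                          tau0 = 0.1, ants = 20L, iterations = 10L,
                          lstep = 20L) {
  stopifnot(alpha > 0, beta > 0, rho > 0, rho <= 1, q0 >= 0, q0 < 1,
            tau0 > 0, ants >= 1, iterations >= 1, lstep >= 1)
  structure(list(alpha = alpha, beta = beta, rho = rho, q0 = q0,
                 tau0 = tau0, ants = as.integer(ants),
                 iterations = as.integer(iterations),
                 lstep = as.integer(lstep)),
            class = "acnet_control")
}

#' Candidate arcs of a partially built network
#'
#' The candidate set contains every absent arc `u -> c` whose addition keeps
#' the graph acyclic and whose heuristic (mutual-information-weighted score
#' gain) is strictly positive. Construction stops when this set is empty —
#' i.e. when no single arc can raise the K2 metric.
#'
#' @param graph current [cbn()].
#' @param data a `discrete_dataset`.
#' @param cache optional [new_score_cache()].
#' @param mi optional precomputed [mutual_information()] table.
#' @return data frame with columns `parent`, `child`, `heuristic`.
#' @export
candidate_arcs <- function(graph, data, cache = NULL, mi = NULL) {
  data <- as_discrete(data)
  if (is.null(mi)) mi <- mutual_information(data)
  v <- length(graph$parents)
  A <- cbn_adjacency(graph)
  reach <- reachability(graph)
  out <- list()
  for (u in seq_len(v)) for (c in seq_len(v)) {
    if (u == c || A[u, c] == 1L) next
    if (reach[c, u]) next  # c already reaches u: adding u -> c closes a cycle
    h <- arc_heuristic(u, c, graph, data, cache, mi)
    if (h > 0) out[[length(out) + 1L]] <- c(u, c, h)
  }
  if (!length(out))
    return(data.frame(parent = integer(0), child = integer(0),
                      heuristic = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(parent = as.integer(m[, 1]), child = as.integer(m[, 2]),
             heuristic = m[, 3])
}

# Boolean reachability matrix: reach[a, b] is TRUE iff a directed path a ~> b
# exists (a != b).
reachability <- function(graph) {
  v <- length(graph$parents)
  A <- cbn_adjacency(graph) > 0
  R <- A
  for (k in seq_len(v))
    R <- R | (R %*% A > 0)
  R
}

#' Pseudo-random proportional arc selection
#'
#' With probability `q0` (exploitation) the candidate maximizing
#' `tau * heuristic^beta` is taken, ties broken towards the smallest
#' `(parent, child)` pair; otherwise (exploration) a candidate is sampled
#' with probability proportional to `tau^alpha * heuristic^beta`.
#'
#' @param candidates data frame from [candidate_arcs()] (non-empty).
#' @param tau pheromone matrix (`tau[u, c]` for arc `u -> c`).
#' @param control an [acnet_control()].
#' @param q optional number in `[0, 1)` replacing the random draw (for
#'   reproducible inspection); `NULL` draws `runif(1)`.
#' @return one row of `candidates` (the selected arc).
#' @export
select_arc <- function(candidates, tau, control = acnet_control(), q = NULL) {
  if (!NROW(candidates)) stop("candidate set is empty")
  if (is.null(q)) q <- stats::runif(1)
  tv <- tau[cbind(candidates$parent, candidates$child)]
  if (q <= control$q0) {
    val <- tv * candidates$heuristic^control$beta
    ord <- order(-val, candidates$parent, candidates$child)
    candidates[ord[1L], ]
  } else {
    w <- tv^control$alpha * candidates$heuristic^control$beta
    candidates[sample.int(nrow(candidates), 1L, prob = w), ]
  }
}

#' Pheromone update rules
#'
#' `local_pheromone_update` applies the on-selection evaporation
#' `tau <- (1 - rho) * tau + rho * tau0` to the single selected arc (its
#' fixed point is `tau0`). `global_pheromone_update` deposits on every arc of
#' the colony-best network `G+`:
#' `tau <- (1 - rho) * tau + rho / |f(G+)|`, where `f(G+)` is its K2 log
#' score; all other entries are unchanged.
#'
#' @param tau pheromone matrix.
#' @param arc length-2 integer vector `(parent, child)`.
#' @param best_graph the colony-best [cbn()] `G+`.
#' @param best_score its K2 log score (negative for any real data set).
#' @param control an [acnet_control()].
#' @return the updated pheromone matrix.
#' @export
local_pheromone_update <- function(tau, arc, control = acnet_control()) {
  u <- arc[[1]]; c <- arc[[2]]
  tau[u, c] <- (1 - control$rho) * tau[u, c] + control$rho * control$tau0
  tau
}

#' @rdname local_pheromone_update
#' @export
global_pheromone_update <- function(tau, best_graph, best_score,
                                    control = acnet_control()) {
  denom <- abs(best_score)
  if (denom == 0) {
    warning("best score is exactly 0; deposit clamped")
    denom <- .Machine$double.xmin
  }
  deposit <- control$rho / denom
  for (c in seq_along(best_graph$parents))
    for (u in best_graph$parents[[c]])
      tau[u, c] <- (1 - control$rho) * tau[u, c] + deposit
  tau
}

#' Construct one network with a single ant
#'
#' Runs one arc-by-arc construction from the empty network under the
#' pseudo-random proportional rule, applying the local pheromone update after
#' each selection. Mainly useful for inspecting the search; [run_colony()]
#' and [acnet()] drive whole colonies.
#'
#' @param data a `discrete_dataset` or object coercible to one.
#' @param control an [acnet_control()].
#' @param tau optional starting pheromone matrix (default `tau0`
#'   everywhere).
#' @param seed integer seed of the ant's random stream.
#' @param cache optional [new_score_cache()].
#' @param mi optional mutual-information table.
#' @return list with `graph` (a [cbn()]), `score`, and `tau` (pheromone after
#'   the local updates).
#' @export
construct_cbn <- function(data, control = acnet_control(), tau = NULL,
                          seed = 1L, cache = NULL, mi = NULL) {
  data <- as_discrete(data)
  v <- ncol(data$levels)
  if (is.null(mi)) mi <- mutual_information(data)
  if (is.null(tau)) tau <- matrix(control$tau0, v, v)
  res <- construct_cbn_cpp(data$levels, data$cardinalities, mi, tau,
                           unclass(control), as.numeric(seed),
                           cache_ptr(cache))
  list(graph = cbn(res$parents, labels = data$labels), score = res$score,
       tau = res$tau)
}

#' Local search on a network
#'
#' First-improvement hill climbing over single-arc additions, deletions and
#' reversals (reversal gain is the combined local-score delta of both
#' endpoint children), sweeping until no move improves or `lstep` sweeps.
#' The returned score is never below the input's and the graph stays acyclic.
#'
#' @param graph a [cbn()].
#' @inheritParams construct_cbn
#' @return list with `graph` and `score`.
#' @export
local_search_cbn <- function(graph, data, control = acnet_control(),
                             cache = NULL) {
  data <- as_discrete(data)
  stopifnot(length(graph$parents) == ncol(data$levels))
  res <- local_search_cpp(data$levels, data$cardinalities, graph$parents,
                          control$lstep, cache_ptr(cache))
  list(graph = cbn(res$parents, labels = data$labels), score = res$score)
}

#' Run a single ant colony on one data set
#'
#' The one-colony reduction of the parallel algorithm (plain ant colony
#' system): `iterations` rounds of `ants` constructions, local search on the
#' iteration best, colony-best bookkeeping and the global pheromone update.
#'
#' @param data a [signal_dataset()], numeric matrix, or `discrete_dataset`.
#' @param control an [acnet_control()].
#' @param seed integer seed.
#' @param bins discretization levels used when `data` is continuous.
#' @return list of class `"colony_result"`: `best_graph`, `best_score`,
#'   `pheromone`, `trace` (per-iteration colony-best scores, non-decreasing),
#'   `cache` (the colony's score cache).
#' @export
run_colony <- function(data, control = acnet_control(), seed = 1L,
                       bins = 3L) {
  data <- as_discrete(data, bins = bins)
  v <- ncol(data$levels)
  mi <- mutual_information(data)
  cache <- new_score_cache()
  state <- list(tau = matrix(control$tau0, v, v),
                best_parents = rep(list(integer(0)), v),
                best_score = -Inf, has_best = FALSE)
  trace <- numeric(control$iterations)
  for (t in seq_len(control$iterations)) {
    res <- colony_iterate_cpp(data$levels, data$cardinalities, mi, state$tau,
                              state$best_parents, state$best_score,
                              state$has_best, unclass(control),
                              as.numeric(seed), t, cache_ptr(cache))
    state <- list(tau = res$tau, best_parents = res$best_parents,
                  best_score = res$best_score, has_best = TRUE)
    trace[t] <- res$best_score
  }
  structure(list(best_graph = cbn(state$best_parents, labels = data$labels),
                 best_score = state$best_score, pheromone = state$tau,
                 trace = trace, cache = cache),
            class = "colony_result")
}

#' @export
print.colony_result <- function(x, ...) {
  cat("Ant colony result: best K2 log score", format(x$best_score),
      "with", narcs(x$best_graph), "arcs after", length(x$trace),
      "iterations\n")
  invisible(x)
}
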