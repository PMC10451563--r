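#' Learn a causal biological network from multiple signal data sets
#'
#' Fits a consensus causal network (a directed acyclic graph over the shared
#' biological nodes) to `N` observational data sets by parallel ant-colony
#' search. Each data set feeds one ant colony that searches DAG space under
#' the K2 Bayesian scoring metric with a mutual-information-weighted
#' heuristic. At the end of every iteration the pheromone matrix of the
#' colony whose best-so-far network scores highest is broadcast to all
#' colonies (pheromone fusion); after the last iteration, the colony-best
#' networks are fused by majority vote: an arc enters the final network iff
#' at least `consensus * N` colonies learned it.
#'
#' Every source of randomness derives deterministically from `seed`
#' (per-colony, per-iteration, per-ant streams), so the result is identical
#' for any `workers` setting or execution order.
#'
#' @param data the `N` data sets: a list of [signal_dataset()]s, numeric
#'   matrices, or file paths; a directory of delimited tables; a single
#'   matrix (then `N = 1`); or a `"sem_benchmark"` from
#'   [generate_benchmark()].
#' @param bins discretization levels per node (see [discretize()]).
#' @param control an [acnet_control()] with the colony parameters.
#' @param consensus consensus fraction in `(0, 1]`; an arc needs support from
#'   at least `consensus * N` colonies (`>=`, so exactly half passes at the
#'   default 0.5).
#' @param seed integer seed.
#' @param workers number of worker processes for the colony loop (forked via
#'   the parallel package; `1` runs serially with persistent score caches).
#' @param fusion_every fuse pheromones at every `fusion_every`-th iteration
#'   (default 1, i.e. after every iteration; useful for sensitivity checks
#'   on the information-sharing schedule).
#' @return Object of class `"acnet"` with components `graph` (the consensus
#'   [cbn()]), `counts` (arc support counts over colony-best networks),
#'   `colonies` (per-colony results), `winner_trace` (winning colony and its
#'   score at each fusion barrier), `control`, `consensus`, `seed`, `labels`.
#' @examples
#' bench <- generate_benchmark(sim_config(v = 5, n_datasets = 4, m = 100))
#' fit <- acnet(bench, control = acnet_control(ants = 5, iterations = 3))
#' fit
#' compare_cbn(fit$graph, bench$truth)
#' @export
acnet <- function(data, bins = 3L, control = acnet_control(),
                  consensus = 0.5, seed = 1L, workers = 1L,
                  fusion_every = 1L) {
  stopifnot(inherits(control, "acnet_control"),
            consensus > 0, consensus <= 1, workers >= 1, fusion_every >= 1)
  datasets <- normalize_datasets(data)
  n <- length(datasets)
  if (n < 1L) stop("at least one data set is required")
  labels <- datasets[[1L]]$labels
  datasets <- lapply(datasets, reconcile_labels, labels = labels)

  discs <- lapply(datasets, discretize, bins = bins)
  mis <- lapply(discs, mutual_information)
  caches <- replicate(n, new_score_cache(), simplify = FALSE)
  v <- length(labels)

  colony_seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i),
                         numeric(1))
  states <- replicate(n, list(best_parents = rep(list(integer(0)), v),
                              best_score = -Inf, has_best = FALSE),
                      simplify = FALSE)
  taus <- replicate(n, matrix(control$tau0, v, v), simplify = FALSE)
  trace <- matrix(NA_real_, control$iterations, 2,
                  dimnames = list(NULL, c("winner", "score")))
  traces <- matrix(NA_real_, control$iterations, n)

  one_colony <- function(i, t) {
    colony_iterate_cpp(discs[[i]]$levels, discs[[i]]$cardinalities,
                       mis[[i]], taus[[i]], states[[i]]$best_parents,
                       states[[i]]$best_score, states[[i]]$has_best,
                       unclass(control), colony_seeds[i], t,
                       cache_ptr(caches[[i]]))
  }
  for (t in seq_len(control$iterations)) {
    res <- if (workers > 1L)
      parallel::mclapply(seq_len(n), one_colony, t = t,
                         mc.cores = as.integer(workers))
    else
      lapply(seq_len(n), one_colony, t = t)
    for (i in seq_len(n))
      states[[i]] <- list(best_parents = res[[i]]$best_parents,
                          best_score = res[[i]]$best_score,
                          has_best = TRUE)
    taus <- lapply(res, `[[`, "tau")
    scores <- vapply(res, `[[`, numeric(1), "best_score")
    w <- which.max(scores)           # ties resolve to the lowest index
    if (t %% fusion_every == 0L) {
      # fusion barrier: every colony adopts the winner's pheromone matrix
      taus <- rep(taus[w], n)
    }
    trace[t, ] <- c(w, scores[w])
    traces[t, ] <- scores
  }

  graphs <- lapply(states, function(s) cbn(s$best_parents, labels = labels))
  cons <- fuse_cbns(graphs, consensus = consensus)
  colonies <- lapply(seq_len(n), function(i)
    structure(list(best_graph = graphs[[i]],
                   best_score = states[[i]]$best_score,
                   trace = traces[, i], cache = caches[[i]]),
              class = "colony_result"))
  structure(list(graph = cons$graph, counts = cons$counts,
                 colonies = colonies, winner_trace = as.data.frame(trace),
                 control = control, consensus = consensus,
                 seed = as.integer(seed), labels = labels,
                 n_colonies = n, pheromone = taus[[1L]],
                 call = match.call()),
            class = "acnet")
}

normalize_datasets <- function(data) {
  if (inherits(data, "sem_benchmark")) return(data$datasets)
  if (inherits(data, "signal_dataset")) return(list(data))
  if (is.matrix(data) || is.data.frame(data))
    return(list(signal_dataset(as.matrix(data))))
  if (is.character(data)) {
    paths <- if (length(data) == 1L && dir.exists(data))
      sort(list.files(data, pattern = "\\.(tsv|csv|txt)$", full.names = TRUE))
    else data
    if (!length(paths)) stop("no data tables found")
    return(lapply(paths, function(p)
      read_signal_table(p, delimiter = if (grepl("\\.csv$", p)) "," else "\t")))
  }
  if (is.list(data))
    return(lapply(data, function(d) {
      if (inherits(d, "signal_dataset")) d else signal_dataset(as.matrix(d))
    }))
  stop("cannot interpret 'data' as a collection of signal data sets")
}

reconcile_labels <- function(d, labels) {
  if (identical(d$labels, labels)) return(d)
  if (!setequal(d$labels, labels))
    stop("data sets do not share the same node labels")
  signal_dataset(d$values[, labels, drop = FALSE], labels = labels,
                 source = d$source)
}

#' Pheromone fusion across colonies
#'
#' Returns (a copy of) the pheromone matrix of the colony whose best network
#' has the highest K2 score; ties resolve to the lowest colony index. At a
#' fusion barrier every colony adopts this matrix for the next iteration.
#'
#' @param results list of per-colony lists with fields `pheromone` and
#'   `best_score`.
#' @return the selected pheromone matrix.
#' @export
fuse_pheromones <- function(results) {
  if (!length(results)) stop("no colony results to fuse")
  dims <- lapply(results, function(r) dim(r$pheromone))
  if (length(unique(dims)) != 1L) stop("pheromone matrices differ in shape")
  scores <- vapply(results, `[[`, numeric(1), "best_score")
  results[[which.max(scores)]]$pheromone
}

#' Majority-vote fusion of learned networks
#'
#' Counts, for every ordered node pair, how many of the `N` colony-best
#' networks contain the arc, and keeps an arc iff its count is at least
#' `consensus * N` (`>=`, so exactly half passes). If both orientations of a
#' pair pass, only the one with the larger count is kept (an exact tie keeps
#' neither). Should the thresholded graph still contain directed cycles,
#' arcs are removed greedily in ascending count order (ties by node-pair
#' index) until it is acyclic, so the result is always a valid CBN.
#'
#' @param graphs list of [cbn()]s on the same node set.
#' @param consensus consensus fraction in `(0, 1]`.
#' @return list of class `"cbn_consensus"`: `counts` (v x v integer matrix),
#'   `graph` (the extracted consensus [cbn()]), `threshold`.
#' @export
fuse_cbns <- function(graphs, consensus = 0.5) {
  stopifnot(length(graphs) >= 1L, consensus > 0, consensus <= 1)
  labels <- graphs[[1L]]$labels
  for (g in graphs)
    if (!identical(g$labels, labels))
      stop("all graphs must share the same node set")
  n <- length(graphs)
  counts <- Reduce(`+`, lapply(graphs, cbn_adjacency))
  thr <- consensus * n
  keep <- counts >= thr
  # orientation conflicts: larger count wins, ties drop both
  v <- length(labels)
  for (u in seq_len(v - 1L)) for (c in seq((u + 1L), v)) {
    if (keep[u, c] && keep[c, u]) {
      if (counts[u, c] > counts[c, u]) keep[c, u] <- FALSE
      else if (counts[c, u] > counts[u, c]) keep[u, c] <- FALSE
      else { keep[u, c] <- FALSE; keep[c, u] <- FALSE }
    }
  }
  # break any remaining cycles: drop weakest-supported cyclic arcs first
  repeat {
    g <- adjacency_to_parents(keep)
    if (!is.null(topo_order_parents(g))) break
    arcs <- which(keep, arr.ind = TRUE)
    cyc <- arcs[apply(arcs, 1L, function(a)
      path_exists_parents(g, a[2L], a[1L])), , drop = FALSE]
    ord <- order(counts[cyc], cyc[, 1L], cyc[, 2L])
    drop <- cyc[ord[1L], ]
    keep[drop[1L], drop[2L]] <- FALSE
  }
  graph <- cbn(adjacency_to_parents(keep), labels = labels)
  structure(list(counts = counts, graph = graph, threshold = thr),
            class = "cbn_consensus")
}

adjacency_to_parents <- function(keep) {
  v <- ncol(keep)
  lapply(seq_len(v), function(c) which(keep[, c]))
}

topo_order_parents <- function(parents) {
  topo_order(structure(list(parents = parents), class = "cbn_raw"))
}

path_exists_parents <- function(parents, from, to) {
  v <- length(parents)
  children <- rep(list(integer(0)), v)
  for (c in seq_len(v)) for (u in parents[[c]])
    children[[u]] <- c(children[[u]], c)
  seen <- logical(v)
  stack <- from
  seen[from] <- TRUE
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in children[[nd]]) {
      if (ch == to) return(TRUE)
      if (!seen[ch]) { seen[ch] <- TRUE; stack <- c(stack, ch) }
    }
  }
  FALSE
}

#' @export
print.cbn_consensus <- function(x, ...) {
  cat("Consensus over colony-best networks (threshold",
      format(x$threshold), "):", narcs(x$graph), "arcs\n")
  invisible(x)
}

#' @export
print.acnet <- function(x, ...) {
  cat("Consensus causal network learned by", x$n_colonies,
      "ant colonies\n")
  cat("  nodes:", length(x$labels), "  arcs:", narcs(x$graph),
      "  consensus threshold: >=",
      format(ceiling(x$consensus * x$n_colonies)), "of", x$n_colonies,
      "colonies\n")
  cat("  best colony K2 log score:",
      format(max(vapply(x$colonies, `[[`, numeric(1), "best_score"))), "\n")
  invisible(x)
}

#' @export
summary.acnet <- function(object, ...) {
  scores <- vapply(object$colonies, `[[`, numeric(1), "best_score")
  arcs <- vapply(object$colonies, function(c) narcs(c$best_graph),
                 numeric(1))
  structure(list(fit = object, colony_scores = scores, colony_arcs = arcs,
                 edges = cbn_edges(object$graph),
                 support = object$counts[cbn_adjacency(object$graph) == 1L]),
            class = "summary.acnet")
}

#' @export
print.summary.acnet <- function(x, ...) {
  print(x$fit)
  cat("\nColony best scores: min", format(min(x$colony_scores)),
      "/ median", format(stats::median(x$colony_scores)),
      "/ max", format(max(x$colony_scores)), "\n")
  cat("Colony best arc counts:", paste(range(x$colony_arcs), collapse = "-"),
      "\n\nConsensus arcs (support of", x$fit$n_colonies, "colonies):\n")
  if (nrow(x$edges)) {
    e <- x$edges
    e$support <- x$support
    print(e, row.names = FALSE)
  } else cat("  (none)\n")
  invisible(x)
}

#' @export
coef.acnet <- function(object, ...) {
  object$counts / object$n_colonies
}

#' @export
plot.acnet <- function(x, ...) {
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(cbn_edges(x$graph), directed = TRUE,
                                       vertices = x$labels)
    igraph::plot.igraph(g, ...)
  } else {
    image(t(cbn_adjacency(x$graph))[, rev(seq_along(x$labels))],
          axes = FALSE, main = "Consensus network adjacency", ...)
  }
  invisible(x)
}
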