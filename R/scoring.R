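#' K2 local score of one node given a parent set
#'
#' Computes the log (natural) of the node's factor of the K2 Bayesian scoring
#' metric over discrete data,
#' \deqn{\sum_j \left[\log\Gamma(r_i) - \log\Gamma(N_{ij}+r_i) +
#'   \sum_k \log\Gamma(N_{ijk}+1)\right],}
#' where \eqn{r_i} is the node's cardinality, \eqn{j} ranges over parent
#' configurations realized in the data, \eqn{N_{ijk}} counts samples with the
#' node at level \eqn{k} under configuration \eqn{j}, and
#' \eqn{N_{ij}=\sum_k N_{ijk}}. Configurations never observed contribute
#' exactly zero in log space, so summing over realized configurations is
#' lossless. Everything is evaluated through `lgamma`; factorials are never
#' formed.
#'
#' @param child node index (1-based).
#' @param parents integer vector of parent node indices (may be empty).
#' @param data a `discrete_dataset` (see [discretize()]) or an object
#'   coercible to one.
#' @param cache optional score cache from [new_score_cache()]; cached values
#'   are bit-identical to fresh recomputation.
#' @return log score in nats (always `<= 0`).
#' @examples
#' d <- discretize(signal_dataset(cbind(a = c(0, 0, 1), b = c(1, 0, 1))))
#' k2_local_score(1, integer(0), d)
#' @export
k2_local_score <- function(child, parents, data, cache = NULL) {
  data <- as_discrete(data)
  v <- ncol(data$levels)
  child <- as.integer(child)
  parents <- as.integer(parents)
  if (length(child) != 1L || is.na(child) || child < 1L || child > v)
    stop("child index out of range")
  if (length(parents) &&
      (anyNA(parents) || any(parents < 1L) || any(parents > v)))
    stop("parent index out of range")
  if (child %in% parents) stop("a node cannot be its own parent")
  if (anyDuplicated(parents)) stop("duplicate parent index")
  k2_local_cpp(data$levels, data$cardinalities, child, parents,
               cache_ptr(cache))
}

#' K2 network score of a CBN
#'
#' The K2 metric decomposes over nodes; the network log score is the sum of
#' [k2_local_score()] over all nodes given their parent sets (the structure
#' prior is taken uniform and dropped as an additive constant).
#'
#' @param graph a [cbn()].
#' @param data a `discrete_dataset` whose node count matches the graph.
#' @inheritParams k2_local_score
#' @return total log score in nats.
#' @export
k2_score <- function(graph, data, cache = NULL) {
  stopifnot(inherits(graph, "cbn"))
  data <- as_discrete(data)
  v <- ncol(data$levels)
  if (length(graph$parents) != v)
    stop("graph has ", length(graph$parents), " nodes but data has ", v)
  s <- 0
  for (c in seq_len(v))
    s <- s + k2_local_score(c, graph$parents[[c]], data, cache)
  s
}

#' Pairwise mutual information of discretized nodes
#'
#' Plug-in estimate of the mutual information (natural log) between every
#' pair of nodes from the empirical joint level frequencies; cells with zero
#' joint count contribute zero. The result is symmetric and nonnegative, and
#' is zero exactly when the empirical joint factorizes.
#'
#' @param data a `discrete_dataset` or an object coercible to one.
#' @param i,j optional node indices; when given, the scalar MI of the pair is
#'   returned instead of the full table.
#' @return symmetric `v x v` matrix in nats (diagonal zero), or a scalar.
#' @export
mutual_information <- function(data, i = NULL, j = NULL) {
  data <- as_discrete(data)
  lev <- data$levels
  v <- ncol(lev)
  m <- nrow(lev)
  pair_mi <- function(a, b) {
    ja <- lev[, a] + 1L
    jb <- lev[, b] + 1L
    ra <- data$cardinalities[a]
    rb <- data$cardinalities[b]
    joint <- matrix(tabulate(ja + ra * (jb - 1L), nbins = ra * rb),
                    nrow = ra) / m
    pa <- rowSums(joint)
    pb <- colSums(joint)
    pos <- joint > 0
    sum(joint[pos] * log(joint[pos] / outer(pa, pb)[pos]))
  }
  if (!is.null(i) || !is.null(j)) {
    if (is.null(i) || is.null(j)) stop("give both i and j, or neither")
    if (i == j) stop("mutual information needs two distinct nodes")
    return(max(0, pair_mi(i, j)))
  }
  mi <- matrix(0, v, v, dimnames = list(data$labels, data$labels))
  for (a in seq_len(v - 1L))
    for (b in seq((a + 1L), v)) {
      val <- max(0, pair_mi(a, b))
      mi[a, b] <- val
      mi[b, a] <- val
    }
  mi
}

#' Heuristic attractiveness of adding one arc
#'
#' The ant heuristic for arc `parent -> child` is the mutual-information
#' weighted local score gain,
#' \deqn{\eta = (1 + \mathrm{Inf}(u, c)) \cdot
#'   [f(c, \Pi(c) \cup u) - f(c, \Pi(c))],}
#' where \eqn{f} is the K2 local score under the graph's current parent set
#' of `child`. Since the weight is at least 1, the heuristic is positive
#' exactly when the arc strictly improves the network score.
#'
#' @param parent,child node indices of the candidate arc.
#' @param graph current [cbn()].
#' @param data a `discrete_dataset`.
#' @param cache optional [new_score_cache()].
#' @param mi optional precomputed [mutual_information()] table.
#' @return scalar heuristic value (sign equals the sign of the score delta).
#' @export
arc_heuristic <- function(parent, child, graph, data, cache = NULL,
                          mi = NULL) {
  data <- as_discrete(data)
  if (is.null(mi)) mi <- mutual_information(data)
  pa <- graph$parents[[child]]
  delta <- k2_local_score(child, sort(c(pa, parent)), data, cache) -
    k2_local_score(child, pa, data, cache)
  (1 + mi[parent, child]) * delta
}

#' Local-score cache
#'
#' A per-dataset memo of K2 local scores keyed by (child, sorted parent set).
#' Sharing a cache across ants, iterations and search phases avoids
#' recounting; cached values are bit-for-bit identical to fresh evaluation,
#' so scoring results never depend on whether a cache is used.
#'
#' @return an object of class `"score_cache"`.
#' @export
new_score_cache <- function() {
  structure(list(ptr = cache_new_cpp()), class = "score_cache")
}

#' @rdname new_score_cache
#' @param cache a `"score_cache"` (or `NULL`).
#' @return `cache_stats`: named vector with `size`, `hits`, `misses`.
#' @export
cache_stats <- function(cache) {
  cache_stats_cpp(cache_ptr(cache))
}

cache_ptr <- function(cache) {
  if (is.null(cache)) return(NULL)
  if (inherits(cache, "score_cache")) return(cache$ptr)
  stop("cache must be NULL or a score_cache")
}

#' @export
print.score_cache <- function(x, ...) {
  s <- cache_stats(x)
  cat("K2 local-score cache:", s[["size"]], "entries,", s[["hits"]], "hits,",
      s[["misses"]], "misses\n")
  invisible(x)
}
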