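#' Causal biological network (CBN) objects
#'
#' A CBN is a directed acyclic graph over labelled biological nodes, stored as
#' per-node parent sets: an arc `u -> c` means node `u` is a parent of node
#' `c`, i.e. a direct causal influence of `u` on `c`.
#'
#' @param parents list of length `v`; element `c` is an integer vector of
#'   parent indices of node `c` (possibly empty).
#' @param labels character vector of `v` unique node labels. Defaults to
#'   `X1..Xv`.
#' @return An object of class `"cbn"`.
#' @examples
#' g <- cbn(list(integer(0), 1L, c(1L, 2L)), labels = c("A", "B", "C"))
#' narcs(g)
#' @export
cbn <- function(parents, labels = NULL) {
  stopifnot(is.list(parents))
  v <- length(parents)
  if (v < 1L) stop("a CBN needs at least one node")
  if (is.null(labels)) labels <- paste0("X", seq_len(v))
  if (length(labels) != v) stop("length(labels) must equal length(parents)")
  if (anyDuplicated(labels)) stop("node labels must be unique")
  parents <- lapply(seq_len(v), function(c) {
    p <- sort(unique(as.integer(parents[[c]])))
    if (length(p) && (min(p) < 1L || max(p) > v))
      stop("parent index out of range for node ", c)
    if (c %in% p) stop("self-arc at node ", labels[c])
    p
  })
  g <- structure(list(parents = parents, labels = as.character(labels)),
                 class = "cbn")
  if (is.null(topo_order(g)))
    stop("parent sets contain a directed cycle; a CBN must be acyclic")
  g
}

#' @rdname cbn
#' @param v number of nodes (for `empty_cbn` when `labels` is missing).
#' @export
empty_cbn <- function(v, labels = NULL) {
  if (missing(v)) v <- length(labels)
  cbn(rep(list(integer(0)), v), labels = labels)
}

#' Build a CBN from a directed edge list
#'
#' @param edges two-column matrix or data frame of arcs (parent, child), given
#'   either as node labels or as 1-based indices.
#' @param labels node labels of the full node set (required when `edges` uses
#'   labels that do not cover all nodes, or is empty).
#' @return A `"cbn"` object.
#' @export
cbn_from_edges <- function(edges, labels) {
  v <- length(labels)
  parents <- rep(list(integer(0)), v)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    from <- as.character(edges[, 1]); to <- as.character(edges[, 2])
    if (all(c(from, to) %in% labels)) {
      ui <- match(from, labels); ci <- match(to, labels)
    } else {
      ui <- suppressWarnings(as.integer(from))
      ci <- suppressWarnings(as.integer(to))
      bad <- which(is.na(ui) | is.na(ci))
      if (length(bad))
        stop("edge (", from[bad[1]], " -> ", to[bad[1]],
             ") refers to an unknown node")
    }
    for (r in seq_along(ui))
      parents[[ci[r]]] <- c(parents[[ci[r]]], ui[r])
  }
  cbn(parents, labels = labels)
}

#' Adjacency matrix of a CBN
#'
#' @param g a `"cbn"` object.
#' @return `v x v` 0/1 integer matrix `A` with `A[u, c] = 1` iff arc `u -> c`.
#' @export
cbn_adjacency <- function(g) {
  stopifnot(inherits(g, "cbn"))
  v <- length(g$parents)
  A <- matrix(0L, v, v, dimnames = list(g$labels, g$labels))
  for (c in seq_len(v)) A[g$parents[[c]], c] <- 1L
  A
}

#' Directed edge list of a CBN
#'
#' @param g a `"cbn"` object.
#' @return data frame with columns `from`, `to` (labels).
#' @export
cbn_edges <- function(g) {
  stopifnot(inherits(g, "cbn"))
  v <- length(g$parents)
  from <- integer(0); to <- integer(0)
  for (c in seq_len(v)) {
    p <- g$parents[[c]]
    from <- c(from, p); to <- c(to, rep.int(c, length(p)))
  }
  data.frame(from = g$labels[from], to = g$labels[to],
             stringsAsFactors = FALSE)
}

#' Number of arcs in a CBN
#' @param g a `"cbn"` object.
#' @export
narcs <- function(g) sum(lengths(g$parents))

# Topological order of the nodes, or NULL if the graph is cyclic.
topo_order <- function(g) {
  v <- length(g$parents)
  indeg <- lengths(g$parents)
  children <- rep(list(integer(0)), v)
  for (c in seq_len(v)) for (u in g$parents[[c]])
    children[[u]] <- c(children[[u]], c)
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, n)
    for (ch in children[[n]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < v) NULL else ord
}

#' Test acyclicity of a parent-set structure
#' @param g a `"cbn"` object.
#' @return `TRUE` if a topological order exists.
#' @export
is_acyclic <- function(g) !is.null(topo_order(g))

#' @export
print.cbn <- function(x, ...) {
  cat("Causal biological network:", length(x$parents), "nodes,",
      narcs(x), "arcs\n")
  e <- cbn_edges(x)
  if (nrow(e)) {
    shown <- utils::head(e, 20L)
    cat(paste0("  ", shown$from, " -> ", shown$to), sep = "\n")
    if (nrow(e) > 20L) cat("  ... and", nrow(e) - 20L, "more\n")
  }
  invisible(x)
}

#' @export
`==.cbn` <- function(e1, e2) {
  identical(e1$labels, e2$labels) && identical(e1$parents, e2$parents)
}
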