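# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: factorial-form K2 over the full
# Cartesian configuration product, plug-in mutual information by double loop,
# and exhaustive DAG enumeration for tiny node counts.

# Naive K2 local score: loops over the FULL Cartesian product of parent level
# combinations (unrealized configurations included) using log-factorials.
k2_local_oracle <- function(child, parents, d) {
  r <- d$cardinalities[child]
  x <- d$levels
  configs <- if (length(parents) == 0L) matrix(0L, 1, 0) else
    as.matrix(expand.grid(lapply(parents,
                                 function(p) 0:(d$cardinalities[p] - 1L))))
  total <- 0
  for (j in seq_len(nrow(configs))) {
    sel <- rep(TRUE, nrow(x))
    for (t in seq_along(parents))
      sel <- sel & x[, parents[t]] == configs[j, t]
    nijk <- vapply(0:(r - 1L), function(k) sum(sel & x[, child] == k),
                   numeric(1))
    total <- total + lfactorial(r - 1) - lfactorial(sum(nijk) + r - 1) +
      sum(lfactorial(nijk))
  }
  total
}

k2_network_oracle <- function(graph, d) {
  sum(vapply(seq_along(graph$parents),
             function(c) k2_local_oracle(c, graph$parents[[c]], d),
             numeric(1)))
}

# Plug-in mutual information by explicit double loop over the level grid.
mi_oracle <- function(i, j, d) {
  m <- nrow(d$levels)
  ri <- d$cardinalities[i]; rj <- d$cardinalities[j]
  total <- 0
  for (a in 0:(ri - 1L)) for (b in 0:(rj - 1L)) {
    pij <- sum(d$levels[, i] == a & d$levels[, j] == b) / m
    if (pij > 0) {
      pi_ <- sum(d$levels[, i] == a) / m
      pj_ <- sum(d$levels[, j] == b) / m
      total <- total + pij * log(pij / (pi_ * pj_))
    }
  }
  total
}

# All DAGs on v nodes (v <= 4), as lists of parent sets.
enumerate_dags <- function(v) {
  off <- which(row(matrix(0, v, v)) != col(matrix(0, v, v)))
  n <- length(off)
  out <- list()
  for (mask in 0:(2^n - 1L)) {
    A <- matrix(0L, v, v)
    A[off] <- as.integer(intToBits(mask))[seq_len(n)]
    parents <- lapply(seq_len(v), function(c) which(A[, c] == 1L))
    g <- try(cbn(parents), silent = TRUE)  # cbn() rejects cyclic structures
    if (!inherits(g, "try-error")) out[[length(out) + 1L]] <- g
  }
  out
}

# Random small discrete data set for oracle-equivalence checks.
random_discrete <- function(v, m, seed, max_card = 3L) {
  set.seed(seed)
  cards <- sample(2:max_card, v, replace = TRUE)
  lev <- vapply(cards, function(r) sample.int(r, m, replace = TRUE) - 1L,
                integer(m))
  # guarantee every level is realized so the cardinalities are honest
  for (j in seq_len(v)) {
    missing <- setdiff(0:(cards[j] - 1L), unique(lev[, j]))
    if (length(missing))
      lev[sample.int(m, length(missing)), j] <- missing
    cards[j] <- length(unique(lev[, j]))
    lev[, j] <- match(lev[, j], sort(unique(lev[, j]))) - 1L
  }
  structure(list(levels = lev, cardinalities = as.integer(cards),
                 labels = paste0("X", seq_len(v))),
            class = "discrete_dataset")
}

# Discrete dataset from explicit columns (no binning involved). Cardinalities
# default to the realized level count; pass `cards` to declare larger spaces
# (levels that exist in principle but are unobserved).
make_discrete <- function(..., cards = NULL) {
  cols <- list(...)
  lev <- do.call(cbind, lapply(cols, as.integer))
  if (is.null(cards))
    cards <- apply(lev, 2L, function(x) length(unique(x)))
  structure(list(levels = lev, cardinalities = as.integer(cards),
                 labels = paste0("X", seq_len(ncol(lev)))),
            class = "discrete_dataset")
}
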