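#' Benchmark configuration for the linear-SEM generator
#'
#' Bundles the parameters of the synthetic benchmark: a random
#' upper-triangular ground-truth DAG with Bernoulli(`edge_prob`) arcs and
#' edge weights uniform on \eqn{[-1.5,-0.5]\cup[0.5,1.5]}, from which `n_datasets`
#' sub-data sets of `m` samples each are drawn by the linear structural
#' equation model \eqn{x = W^\top x + \lambda} with unit-variance noise.
#'
#' @param v number of nodes (`>= 2`).
#' @param n_datasets number of sub-data sets `N` (one per ant colony).
#' @param m samples per sub-data set (default 200).
#' @param edge_prob probability of each upper-triangular arc (default 0.5).
#' @param noise `"gaussian"` (default) or `"gumbel"` (a standardized Gumbel:
#'   zero mean, unit variance — the conventional non-Gaussian choice).
#' @param seed integer seed; fully determines the benchmark.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(v, n_datasets = 20L, m = 200L, edge_prob = 0.5,
                       noise = c("gaussian", "gumbel"), seed = 1L) {
  noise <- match.arg(noise)
  v <- as.integer(v); n_datasets <- as.integer(n_datasets); m <- as.integer(m)
  stopifnot(v >= 2L, n_datasets >= 1L, m >= 1L,
            edge_prob >= 0, edge_prob <= 1)
  structure(list(v = v, n_datasets = n_datasets, m = m,
                 edge_prob = edge_prob, noise = noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random ground-truth linear-SEM model
#'
#' Draws a strictly upper-triangular weight matrix `W` (hence an acyclic
#' generating order): each upper entry is present with probability
#' `edge_prob`, and a present entry gets an independent weight whose sign is
#' a fair coin and whose magnitude is uniform on `[0.5, 1.5]` — i.e. uniform
#' on \eqn{[-1.5,-0.5]\cup[0.5,1.5]}. A uniformly random node permutation is
#' drawn and stored; data columns and the exported truth graph are expressed
#' in this observed order so downstream code never sees the generating
#' (topological) order.
#'
#' @param v number of nodes.
#' @param edge_prob arc probability for each upper-triangular entry.
#' @param seed integer seed.
#' @return list of class `"sem_truth"` with fields `W` (weights, generation
#'   order), `adjacency` (generation order), `perm` (observed column `j` is
#'   generation node `perm[j]`), `labels`, `seed`.
#' @export
generate_ground_truth <- function(v, edge_prob = 0.5, seed = 1L) {
  v <- as.integer(v)
  stopifnot(v >= 1L)
  with_seed(seed, {
    W <- matrix(0, v, v)
    if (v >= 2L) {
      up <- which(upper.tri(W))
      present <- up[stats::runif(length(up)) < edge_prob]
      if (length(present)) {
        sign <- ifelse(stats::runif(length(present)) < 0.5, -1, 1)
        mag <- stats::runif(length(present), 0.5, 1.5)
        W[present] <- sign * mag
      }
    }
    perm <- sample.int(v)
    structure(list(W = W, adjacency = (W != 0) * 1L, perm = perm,
                   labels = paste0("X", seq_len(v)),
                   seed = as.integer(seed)),
              class = "sem_truth")
  })
}

#' Ground-truth CBN in observed coordinates
#'
#' @param model a `"sem_truth"` from [generate_ground_truth()].
#' @return a [cbn()] whose arcs are the nonzero weights of `W`, re-indexed by
#'   the stored observation permutation.
#' @export
truth_cbn <- function(model) {
  stopifnot(inherits(model, "sem_truth"))
  A_obs <- model$adjacency[model$perm, model$perm, drop = FALSE]
  idx <- which(A_obs == 1L, arr.ind = TRUE)
  cbn_from_edges(cbind(idx[, 1], idx[, 2]), labels = model$labels)
}

#' @export
print.sem_truth <- function(x, ...) {
  cat("Linear-SEM ground truth:", ncol(x$W), "nodes,",
      sum(x$adjacency), "arcs (seed", x$seed, ")\n")
  invisible(x)
}

#' Sample one data set from a linear-SEM ground truth
#'
#' Each sample solves \eqn{x = W^\top x + \lambda} by forward substitution in
#' the generating (topological) order: \eqn{x_c = \sum_u W_{uc} x_u +
#' \lambda_c}. Noise \eqn{\lambda} has unit variance per node: standard
#' Gaussian, or standardized Gumbel for the non-Gaussian family. Columns are
#' then reordered by the model's stored permutation.
#'
#' @param model a `"sem_truth"`.
#' @param m number of samples.
#' @param noise `"gaussian"` or `"gumbel"`.
#' @param seed integer seed.
#' @return a [signal_dataset()] with `m` rows in observed column order.
#' @export
sample_signal_data <- function(model, m = 200L, noise = "gaussian",
                               seed = 1L) {
  stopifnot(inherits(model, "sem_truth"))
  m <- as.integer(m)
  stopifnot(m >= 1L)
  v <- ncol(model$W)
  lam <- with_seed(seed, switch(
    noise,
    gaussian = matrix(stats::rnorm(m * v), m, v),
    gumbel = {
      b <- sqrt(6) / pi                    # scale for unit variance
      u <- matrix(stats::runif(m * v), m, v)
      b * (-log(-log(u)) - 0.5772156649015329)  # centred: zero mean
    },
    stop("unknown noise family: ", noise)))
  x <- matrix(0, m, v)
  for (c in seq_len(v)) {
    drive <- if (c > 1L)
      x[, seq_len(c - 1L), drop = FALSE] %*% model$W[seq_len(c - 1L), c]
    else 0
    x[, c] <- drive + lam[, c]
  }
  signal_dataset(x[, model$perm, drop = FALSE], labels = model$labels,
                 source = paste0("sem_seed", seed))
}

#' Generate a full multi-data-set benchmark
#'
#' One shared ground truth (and one shared observation permutation — the
#' sub-data sets are repeated observations of the same biological system),
#' with independently seeded noise per sub-data set.
#'
#' @param cfg a [sim_config()].
#' @return list of class `"sem_benchmark"`: `model` (the `"sem_truth"`),
#'   `truth` (ground-truth [cbn()] in observed coordinates), `datasets`
#'   (list of `N` [signal_dataset()]s), `config`.
#' @export
generate_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  model <- generate_ground_truth(cfg$v, cfg$edge_prob, seed = cfg$seed)
  datasets <- lapply(seq_len(cfg$n_datasets), function(k) {
    d <- sample_signal_data(model, m = cfg$m, noise = cfg$noise,
                            seed = derive_seed(cfg$seed, k))
    d$source <- paste0("subset", k)
    d
  })
  structure(list(model = model, truth = truth_cbn(model),
                 datasets = datasets, config = cfg),
            class = "sem_benchmark")
}

#' @export
print.sem_benchmark <- function(x, ...) {
  cat("Linear-SEM benchmark:", x$config$v, "nodes,",
      length(x$datasets), "sub-data sets x", x$config$m, "samples,",
      narcs(x$truth), "truth arcs,", x$config$noise, "noise\n")
  invisible(x)
}

# Deterministic derived seed, kept inside the 32-bit signed integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}
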