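# A tiny dataset with a strong X1 -> X2 dependence and an independent X3.
dep_toy <- function(m = 60, seed = 1) {
  set.seed(seed)
  x1 <- sample(0:2, m, replace = TRUE)
  x2 <- (x1 + (runif(m) < 0.1)) %% 3
  x3 <- sample(0:2, m, replace = TRUE)
  make_discrete(x1, x2, x3)
}

test_that("candidate arcs are improving, absent, and acyclicity-safe", {
  d <- dep_toy()
  g0 <- empty_cbn(labels = d$labels)
  cand <- candidate_arcs(g0, d)
  # strong dependence: both orientations of the X1-X2 arc are candidates
  expect_true(any(cand$parent == 1 & cand$child == 2))
  expect_true(any(cand$parent == 2 & cand$child == 1))
  expect_true(all(cand$heuristic > 0))

  # a 3-cycle-tempting graph: X1 -> X2 -> X3 present; X3 -> X1 must not appear
  g <- cbn(list(integer(0), 1L, 2L), labels = d$labels)
  cand2 <- candidate_arcs(g, d)
  expect_false(any(cand2$parent == 3 & cand2$child == 1))
  for (r in seq_len(nrow(cand2))) {
    g2 <- g
    g2$parents[[cand2$child[r]]] <-
      c(g2$parents[[cand2$child[r]]], cand2$parent[r])
    expect_no_error(cbn(g2$parents, labels = d$labels))
  }
})

test_that("a saturated graph yields an empty candidate set", {
  d <- dep_toy()
  res <- local_search_cbn(construct_cbn(d, seed = 1)$graph, d)
  cand <- candidate_arcs(res$graph, d)
  expect_equal(nrow(cand), 0L)  # construction + local search exhaust gains
})

test_that("arc selection follows the pseudo-random proportional rule", {
  cand <- data.frame(parent = c(1L, 2L, 3L), child = c(2L, 3L, 1L),
                     heuristic = c(2, 1, 3))
  tau <- matrix(0.1, 3, 3)
  tau[1, 2] <- 0.5; tau[2, 3] <- 0.9; tau[3, 1] <- 0.2
  ctl <- acnet_control(beta = 2, alpha = 1.2)
  # exploitation (q below q0): brute-force argmax of tau * eta^beta
  vals <- c(0.5 * 4, 0.9 * 1, 0.2 * 9)
  pick <- select_arc(cand, tau, ctl, q = 0)
  expect_equal(which.max(vals), 1L)
  expect_equal(c(pick$parent, pick$child), c(1L, 2L))
  # single candidate is forced for any q
  expect_equal(select_arc(cand[2, ], tau, ctl, q = 0.99)$parent, 2L)
  # exploration: sampled frequencies match tau^alpha * eta^beta weights
  w <- c(0.5^1.2 * 4, 0.9^1.2 * 1, 0.2^1.2 * 9)
  p <- w / sum(w)
  set.seed(8)
  draws <- replicate(4000, select_arc(cand, tau, ctl, q = 0.9)$parent)
  freq <- tabulate(draws, 3) / 4000
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / 4000)))
})

test_that("local pheromone update follows the evaporation rule", {
  ctl <- acnet_control(rho = 0.35, tau0 = 0.1)
  tau <- matrix(1, 3, 3)
  t2 <- local_pheromone_update(tau, c(1L, 2L), ctl)
  expect_equal(t2[1, 2], 0.65 * 1 + 0.35 * 0.1)  # 0.685
  untouched <- matrix(TRUE, 3, 3); untouched[1, 2] <- FALSE
  expect_equal(t2[untouched], tau[untouched])    # only the selected arc moves
  # tau0 is the fixed point, approached monotonically under repetition
  t3 <- matrix(ctl$tau0, 3, 3)
  expect_equal(local_pheromone_update(t3, c(1L, 2L), ctl), t3)
  x <- 1
  for (i in 1:50) x <- 0.65 * x + 0.35 * 0.1
  expect_lt(abs(x - 0.1), 1e-8)
})

test_that("global pheromone update deposits only on the best graph's arcs", {
  ctl <- acnet_control(rho = 0.35)
  g <- cbn(list(integer(0), 1L, integer(0)))
  tau <- matrix(0.1, 3, 3)
  t2 <- global_pheromone_update(tau, g, best_score = -100, control = ctl)
  expect_equal(t2[1, 2], 0.65 * 0.1 + 0.35 * 0.01)  # 0.0685
  expect_identical(t2[2, 1], 0.1)                   # untouched arcs unchanged
  # a better (less negative) score deposits more
  t3 <- global_pheromone_update(tau, g, best_score = -50, control = ctl)
  expect_gt(t3[1, 2], t2[1, 2])
  expect_warning(global_pheromone_update(tau, g, 0, ctl), "clamped")
})

test_that("construction adds only improving arcs and stays acyclic", {
  d <- dep_toy(m = 80, seed = 3)
  res <- construct_cbn(d, seed = 11)
  expect_true(is_acyclic(res$graph))
  expect_gt(res$score, k2_score(empty_cbn(labels = d$labels), d))
  expect_equal(res$score, k2_score(res$graph, d))

  # mutually independent columns at large m: (near-)empty graph
  set.seed(2)
  ind <- make_discrete(sample(0:2, 600, TRUE), sample(0:2, 600, TRUE),
                       sample(0:2, 600, TRUE))
  res2 <- construct_cbn(ind, seed = 1)
  expect_lte(narcs(res2$graph), 1L)
})

test_that("greedy reduction finds the enumerated K2 optimum", {
  # q0 ~ 1 with uniform pheromone is deterministic greedy K2 search
  set.seed(4)
  b <- generate_benchmark(sim_config(v = 3, n_datasets = 1, m = 120,
                                     seed = 17))
  d <- discretize(b$datasets[[1]])
  ctl <- acnet_control(q0 = 0.999)
  res <- construct_cbn(d, control = ctl, seed = 2)
  res <- local_search_cbn(res$graph, d, ctl)
  dags <- enumerate_dags(3)
  best <- max(vapply(dags, k2_score, numeric(1), data = d))
  expect_equal(res$score, best, tolerance = 1e-9)
})

test_that("local search is monotone, acyclic, and fixes local optima", {
  d <- dep_toy(m = 100, seed = 5)
  g <- cbn(list(2L, integer(0), integer(0)), labels = d$labels)  # X2 -> X1
  s0 <- k2_score(g, d)
  res <- local_search_cbn(g, d)
  expect_gte(res$score, s0)
  expect_true(is_acyclic(res$graph))
  # running again from the optimum changes nothing
  res2 <- local_search_cbn(res$graph, d)
  expect_identical(res2$graph$parents, res$graph$parents)
})

test_that("reversal repairs a wrongly oriented arc when scores demand it", {
  # construct data where X1 -> X2 scores strictly higher than X2 -> X1
  found <- FALSE
  for (seed in 1:20) {
    d <- dep_toy(m = 60, seed = seed)
    fwd <- cbn(list(integer(0), 1L, integer(0)), labels = d$labels)
    bwd <- cbn(list(2L, integer(0), integer(0)), labels = d$labels)
    if (k2_score(fwd, d) > k2_score(bwd, d) + 1e-9) {
      res <- local_search_cbn(bwd, d)
      expect_gte(res$score, k2_score(fwd, d) - 1e-9)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("colony runs are deterministic with a non-decreasing best trace", {
  d <- dep_toy(m = 80, seed = 7)
  ctl <- acnet_control(ants = 5, iterations = 4)
  r1 <- run_colony(d, ctl, seed = 31)
  r2 <- run_colony(d, ctl, seed = 31)
  expect_identical(r1$best_graph$parents, r2$best_graph$parents)
  expect_identical(r1$best_score, r2$best_score)
  expect_identical(r1$pheromone, r2$pheromone)
  expect_true(all(diff(r1$trace) >= 0))
  expect_true(all(r1$pheromone > 0))
  # the reported best score is reproducible from scratch
  expect_equal(r1$best_score, k2_score(r1$best_graph, d), tolerance = 0)
})

test_that("ant graphs and colony bests attain the enumerated optimum", {
  hits <- 0L
  for (seed in 1:10) {
    b <- generate_benchmark(sim_config(v = 3, n_datasets = 1, m = 100,
                                       seed = seed))
    d <- discretize(b$datasets[[1]])
    r <- run_colony(d, acnet_control(ants = 10, iterations = 5), seed = seed)
    expect_true(is_acyclic(r$best_graph))
    best <- max(vapply(enumerate_dags(3), k2_score, numeric(1), data = d))
    if (abs(r$best_score - best) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
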