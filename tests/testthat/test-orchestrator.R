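test_that("pheromone fusion broadcasts the best colony's matrix", {
  mk <- function(val, score) list(pheromone = matrix(val, 3, 3),
                                  best_score = score)
  # one strictly best colony: its matrix is returned element-for-element
  out <- fuse_pheromones(list(mk(1, -50), mk(2, -10), mk(3, -90)))
  expect_identical(out, matrix(2, 3, 3))
  # all tied: the first colony wins
  out2 <- fuse_pheromones(list(mk(5, -10), mk(6, -10)))
  expect_identical(out2, matrix(5, 3, 3))
  expect_error(fuse_pheromones(list(mk(1, -1),
                                    list(pheromone = matrix(1, 2, 2),
                                         best_score = -1))),
               "shape")
})

test_that("network fusion applies the majority-vote extraction rule", {
  labs <- c("A", "B", "C")
  g1 <- cbn_from_edges(rbind(c("A", "B"), c("B", "C")), labs)
  g2 <- cbn_from_edges(rbind(c("A", "B")), labs)
  # unanimity: counts in {0, N} and the common graph returned
  same <- fuse_cbns(list(g1, g1, g1))
  expect_identical(same$graph$parents, g1$parents)
  expect_true(all(same$counts %in% c(0L, 3L)))
  # exactly-half passes (>= threshold): arc in 1 of 2 graphs is kept
  half <- fuse_cbns(list(g1, g2), consensus = 0.5)
  expect_identical(half$graph$parents, g1$parents)
})

test_that("orientation conflicts keep the larger count, ties keep neither", {
  labs <- c("A", "B")
  ab <- cbn_from_edges(rbind(c("A", "B")), labs)
  ba <- cbn_from_edges(rbind(c("B", "A")), labs)
  res <- fuse_cbns(list(ab, ab, ab, ba, ba), consensus = 0.4)
  expect_equal(cbn_edges(res$graph)$from, "A")  # 3 beats 2
  tie <- fuse_cbns(list(ab, ab, ba, ba), consensus = 0.5)
  expect_equal(narcs(tie$graph), 0L)            # 2 vs 2 drops both
})

test_that("consensus cycles are broken by dropping weak arcs", {
  labs <- c("A", "B", "C")
  cyc1 <- cbn_from_edges(rbind(c("A", "B"), c("B", "C")), labs)
  cyc2 <- cbn_from_edges(rbind(c("B", "C"), c("C", "A")), labs)
  cyc3 <- cbn_from_edges(rbind(c("C", "A"), c("A", "B")), labs)
  res <- fuse_cbns(list(cyc1, cyc2, cyc3), consensus = 0.5)
  expect_true(is_acyclic(res$graph))
  expect_lt(narcs(res$graph), 3L)
})

test_that("raising the consensus threshold never adds arcs", {
  set.seed(30)
  labs <- paste0("X", 1:4)
  graphs <- lapply(1:6, function(i) {
    b <- generate_ground_truth(4, 0.5, seed = i)
    truth_cbn(b)
  })
  prev <- Inf
  for (thr in c(0.3, 0.5, 0.7, 0.9, 1)) {
    n <- narcs(fuse_cbns(graphs, consensus = thr)$graph)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("a single data set reduces to one plain ant colony", {
  b <- generate_benchmark(sim_config(v = 4, n_datasets = 1, m = 100,
                                     seed = 3))
  ctl <- acnet_control(ants = 5, iterations = 3)
  fit <- acnet(b, control = ctl, seed = 9)
  expect_equal(fit$n_colonies, 1L)
  # fusing one graph returns it unchanged
  expect_identical(fit$graph$parents, fit$colonies[[1]]$best_graph$parents)
})

test_that("serial and parallel execution are bit-identical", {
  b <- generate_benchmark(sim_config(v = 4, n_datasets = 4, m = 80,
                                     seed = 21))
  ctl <- acnet_control(ants = 4, iterations = 3)
  serial <- acnet(b, control = ctl, seed = 5, workers = 1)
  par2 <- acnet(b, control = ctl, seed = 5, workers = 2)
  expect_identical(serial$graph$parents, par2$graph$parents)
  expect_identical(serial$counts, par2$counts)
  expect_identical(serial$winner_trace, par2$winner_trace)
  expect_identical(serial$pheromone, par2$pheromone)
  expect_identical(
    lapply(serial$colonies, function(c) c$best_score),
    lapply(par2$colonies, function(c) c$best_score))
})

test_that("full fits are seed-deterministic and structurally sound", {
  b <- generate_benchmark(sim_config(v = 5, n_datasets = 6, m = 80,
                                     seed = 13))
  ctl <- acnet_control(ants = 4, iterations = 3)
  f1 <- acnet(b, control = ctl, seed = 2)
  f2 <- acnet(b, control = ctl, seed = 2)
  expect_identical(f1$graph$parents, f2$graph$parents)
  expect_identical(f1$counts, f2$counts)
  expect_true(is_acyclic(f1$graph))
  for (col in f1$colonies) expect_true(is_acyclic(col$best_graph))
  expect_true(all(f1$pheromone > 0))
  # exactly one fusion barrier per iteration, winner scores non-decreasing
  expect_equal(nrow(f1$winner_trace), ctl$iterations)
  expect_true(all(diff(f1$winner_trace$score) >= 0))
  # every consensus arc meets the count threshold
  A <- cbn_adjacency(f1$graph)
  expect_true(all(f1$counts[A == 1L] >= 0.5 * f1$n_colonies))
})

test_that("the consensus beats a random graph of the same density", {
  b <- generate_benchmark(sim_config(v = 5, n_datasets = 20, m = 200,
                                     seed = 2))
  fit <- acnet(b, seed = 2)
  f1_fit <- compare_cbn(fit$graph, b$truth)$f1
  set.seed(99)
  f1_rand <- mean(replicate(200, {
    k <- narcs(fit$graph)
    # random DAG with the same arc count: random node pairs oriented by a
    # random total order (always acyclic)
    ord <- sample.int(5)
    e <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
    pick <- e[sample.int(nrow(e), min(k, nrow(e))), , drop = FALSE]
    fwd <- ord[pick[, 1]] < ord[pick[, 2]]
    edges <- cbind(ifelse(fwd, pick[, 1], pick[, 2]),
                   ifelse(fwd, pick[, 2], pick[, 1]))
    g <- cbn_from_edges(cbind(paste0("X", edges[, 1]),
                              paste0("X", edges[, 2])), fit$labels)
    compare_cbn(g, b$truth)$f1
  }))
  expect_gt(f1_fit, f1_rand + 0.15)
})

test_that("a sparser fusion schedule still yields a valid deterministic fit", {
  b <- generate_benchmark(sim_config(v = 4, n_datasets = 3, m = 60,
                                     seed = 19))
  ctl <- acnet_control(ants = 3, iterations = 4)
  f1 <- acnet(b, control = ctl, seed = 1, fusion_every = 2)
  f2 <- acnet(b, control = ctl, seed = 1, fusion_every = 2)
  expect_identical(f1$graph$parents, f2$graph$parents)
  expect_true(is_acyclic(f1$graph))
})

test_that("label reconciliation and input validation work", {
  b <- generate_benchmark(sim_config(v = 4, n_datasets = 2, m = 60,
                                     seed = 8))
  shuffled <- b$datasets
  shuffled[[2]] <- signal_dataset(shuffled[[2]]$values[, c(3, 1, 2, 4)])
  ctl <- acnet_control(ants = 3, iterations = 2)
  expect_no_error(acnet(shuffled, control = ctl, seed = 1))
  bad <- shuffled
  colnames(bad[[2]]$values)[1] <- "zzz"
  bad[[2]]$labels[1] <- "zzz"
  expect_error(acnet(bad, control = ctl, seed = 1), "labels")
  expect_error(acnet(list(), control = ctl), "at least one")
})
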