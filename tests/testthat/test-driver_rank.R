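test_that("degree-biased transition probabilities follow hand normalization", {
  tri <- gene_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  tm <- degree_biased_transition(tri)
  # regular graph: reduces to the plain random walk
  expect_equal(unname(tm[, "A"]), c(0, 0.5, 0.5))
  expect_equal(unname(colSums(tm)), rep(1, 3))

  star <- gene_network(rbind(c("H", "L1"), c("H", "L2"), c("H", "L3")))
  tms <- degree_biased_transition(star)
  expect_equal(tms["H", "L1"], 1)   # leaves must step to the hub
  expect_equal(unname(tms[c("L1", "L2", "L3"), "H"]), rep(1 / 3, 3))

  path3 <- gene_network(rbind(c("A", "B"), c("B", "C")))
  tmp <- degree_biased_transition(path3)
  expect_equal(tmp["A", "B"], 0.5)
  expect_equal(tmp["C", "B"], 0.5)
  expect_equal(tmp["B", "A"], 1)
})

test_that("restart vectors normalize over seeds present in the DCN", {
  net <- path_network()
  r <- restart_vector(net, gene_set("s", c("A", "B", "C", "Z")))
  expect_equal(sum(r), 1)
  expect_equal(unname(r[c("A", "B", "C")]), rep(1 / 3, 3))
  expect_equal(unname(r["D"]), 0)
  r1 <- restart_vector(net, gene_set("s", "B"))
  expect_equal(unname(r1["B"]), 1)
  expect_error(restart_vector(net, gene_set("s", c("X", "Y"))),
               "no seed gene")
})

test_that("expression-weighted restart mass is proportional to |moderated t|", {
  net <- generate_ppi(50, 2, seed = 3)
  truth <- plant_modules(net, 1, 8, seed = 3)
  truth$planted_degs$D1 <- truth$modules$D1[1:2]
  study <- generate_expression(net, truth, n_case = 8, n_control = 8,
                               delta = 2, seed = 3)
  seeds <- gene_set("D1", truth$modules$D1[1:4])
  r <- restart_vector(net, seeds, mode = "expression", study = study)
  expect_equal(sum(r), 1)
  deg_tab <- run_diffexp(study)
  w <- abs(deg_tab$t_mod[match(seeds$genes, deg_tab$gene)])
  expect_equal(unname(r[seeds$genes]), w / sum(w))
  expect_true(all(r[setdiff(names(r), seeds$genes)] == 0))
})

test_that("power iteration matches the direct linear-solve oracle", {
  for (seed in 1:25) {
    net <- random_walk_graph(10 + seed, 0.12, seed = seed)
    seeds <- withr::with_seed(seed, sample(net$nodes, 3))
    got <- random_walk_scores(net, gene_set("s", seeds), keep_trace = TRUE)
    oracle <- oracle_rwr(net, seeds, damping = 0.85)
    expect_equal(got$score, unname(oracle[got$gene]), tolerance = 1e-8)
    # conservation at every iteration
    expect_true(all(abs(attr(got, "trace") - 1) < 1e-9))
    expect_equal(sum(got$score), 1, tolerance = 1e-9)
    expect_identical(got$rank, seq_len(nrow(got)))
  }
})

test_that("a vanishing damping factor returns the restart vector", {
  net <- random_walk_graph(20, 0.15, seed = 4)
  seeds <- withr::with_seed(4, sample(net$nodes, 4))
  got <- random_walk_scores(net, gene_set("s", seeds),
                            walk_config(damping = 1e-12))
  r <- restart_vector(net, gene_set("s", seeds))
  expect_equal(got$score, unname(r[got$gene]), tolerance = 1e-9)
})

test_that("automorphic nodes receive equal scores", {
  # barbell: two triangles joined by a bridge, seeds symmetric
  edges <- rbind(c("A1", "A2"), c("A2", "A3"), c("A1", "A3"),
                 c("B1", "B2"), c("B2", "B3"), c("B1", "B3"),
                 c("A1", "B1"))
  net <- gene_network(edges)
  got <- random_walk_scores(net, gene_set("s", c("A2", "B2")))
  score <- stats::setNames(got$score, got$gene)
  expect_equal(score[["A1"]], score[["B1"]], tolerance = 1e-9)
  expect_equal(score[["A2"]], score[["B2"]], tolerance = 1e-9)
  expect_equal(score[["A3"]], score[["B3"]], tolerance = 1e-9)
})

test_that("the hub of a star outranks non-seed leaves", {
  star <- gene_network(cbind("H", paste0("L", 1:6)))
  got <- random_walk_scores(star, gene_set("s", "L1"))
  score <- stats::setNames(got$score, got$gene)
  expect_true(all(score[["H"]] > score[paste0("L", 2:6)]))
})

test_that("top_candidates truncates, flags seeds and breaks ties by id", {
  net <- random_walk_graph(30, 0.12, seed = 6)
  seeds <- withr::with_seed(6, sample(net$nodes, 3))
  ranking <- random_walk_scores(net, gene_set("s", seeds))
  expect_identical(top_candidates(ranking, 1e6), ranking$gene)
  expect_identical(top_candidates(ranking, 1), ranking$gene[1])
  expect_identical(top_candidates(ranking, 5), ranking$gene[1:5])
  expect_identical(ranking$is_seed, ranking$gene %in% seeds)
  # equal scores order lexicographically (star leaves are exchangeable)
  star <- gene_network(cbind("H", paste0("L", 1:5)))
  r2 <- random_walk_scores(star, gene_set("s", "H"))
  leaves <- r2$gene[r2$gene != "H"]
  expect_identical(leaves, sort(leaves))
})

test_that("non-convergence within max_iter is an error", {
  net <- path_network()
  expect_error(
    random_walk_scores(net, gene_set("s", "A"),
                       walk_config(tol = 1e-14, max_iter = 2L)),
    "did not converge")
})

test_that("planted drivers are strongly enriched at the top of the ranking", {
  # module-invariant benchmark: mean precision-at-20 over replicates must
  # beat 10x the uniform-random expectation on the same candidate pool
  folds <- numeric(0)
  driver_beats_peripheral <- logical(0)
  for (seed in 1:20) {
    bench <- synthetic_benchmark(seed = 1000 + seed, n_diseases = 2)
    d <- "D1"
    study <- bench$studies[[d]]
    sel <- differential_coexpression_edges(study, bench$network$edges)
    dcn <- build_dcn(bench$network, sel)
    seeds <- intersect(bench$truth$modules[[d]], dcn$nodes)
    ranking <- random_walk_scores(dcn, gene_set(d, seeds))
    drivers <- bench$truth$planted_drivers[[d]]
    top20 <- top_candidates(ranking, 20)
    prec <- mean(top20 %in% drivers)
    chance <- sum(drivers %in% dcn$nodes) / length(dcn$nodes)
    folds <- c(folds, prec / chance)
    # a wired driver should outrank a random non-seed peripheral gene
    periph <- withr::with_seed(seed, sample(setdiff(
      dcn$nodes, c(seeds, drivers)), 1))
    rk <- stats::setNames(ranking$rank, ranking$gene)
    present <- intersect(drivers, dcn$nodes)
    driver_beats_peripheral <- c(driver_beats_peripheral,
                                 min(rk[present]) < rk[[periph]])
  }
  expect_gt(mean(folds), 10)
  expect_gte(mean(driver_beats_peripheral), 0.95)
})
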