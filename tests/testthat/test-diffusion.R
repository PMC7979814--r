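test_that("directed view makes the focal a source and other entities sinks", {
  g <- toy_graph()
  v <- directed_view(g, "c1")
  # no in-edges into the focal
  expect_false(any(v$ids[v$j] == "c1"))
  # other drugs and diseases have no out-edges and sit in the sink set
  others <- c("c2", "d1", "d2")
  expect_false(any(v$ids[v$i] %in% others))
  expect_true(all(match(others, v$ids) %in% v$sinks))
  expect_error(directed_view(g, "p1"), "drug or disease")
})

test_that("a protein whose only neighbor is the focal becomes a sink", {
  dp <- data.frame(node_1 = "c1", node_1_type = "drug",
                   node_2 = c("p1", "p2"), node_2_type = "protein")
  xp <- data.frame(node_1 = "d1", node_1_type = "disease",
                   node_2 = "p2", node_2_type = "protein")
  ppi <- NULL
  g <- suppressMessages(assemble_graph(dp, xp,
         data.frame(node_1 = "p2", node_1_type = "protein",
                    node_2 = "p3", node_2_type = "protein")))
  v <- directed_view(g, "c1")
  expect_true(match("p1", v$ids) %in% v$sinks)   # p1 only touches the focal
  expect_false(match("p2", v$ids) %in% v$sinks)
})

test_that("transition probabilities follow the type-then-neighbor split", {
  # protein p0 with 1 drug, 2 protein and 3 function out-neighbors
  dp <- data.frame(node_1 = "c1", node_1_type = "drug",
                   node_2 = c("p0", "px"), node_2_type = "protein")
  ppi <- data.frame(node_1 = "p0", node_1_type = "protein",
                    node_2 = c("pa", "pb"), node_2_type = "protein")
  ann <- data.frame(node_1 = "p0", node_1_type = "protein",
                    node_2 = c("f1", "f2", "f3"), node_2_type = "biological_function")
  hier <- data.frame(node_1 = c("f2", "f3"), node_1_type = "biological_function",
                     node_2 = "f1", node_2_type = "biological_function")
  xp <- data.frame(node_1 = "d1", node_1_type = "disease",
                   node_2 = "pa", node_2_type = "protein")
  g <- suppressMessages(assemble_graph(dp, xp, ppi, ann, hier))
  cfg <- edge_weights(w_drug = 3.21, w_disease = 3.54, w_protein = 4.40,
                      w_biological_function = 6.58)
  v <- directed_view(g, "d1")    # focal elsewhere so p0 keeps the drug edge
  M <- transition_matrix(v, cfg)
  i0 <- match("p0", v$ids)
  total <- 3.21 + 4.40 + 6.58
  expect_equal(M[i0, match("c1", v$ids)], 3.21 / total, tolerance = 1e-12)
  expect_equal(M[i0, match("pa", v$ids)], 4.40 / total / 2, tolerance = 1e-12)
  expect_equal(M[i0, match("f1", v$ids)], 6.58 / total / 3, tolerance = 1e-12)
  expect_equal(M[i0, match("c1", v$ids)], 0.22621, tolerance = 1e-4)
  expect_equal(M[i0, match("pa", v$ids)], 0.15504, tolerance = 1e-4)
  expect_equal(M[i0, match("f1", v$ids)], 0.15457, tolerance = 1e-4)

  # with equal weights the split is uniform over adjacent types, then
  # uniform within a type; a single-type node reduces to 1/k
  ucfg <- edge_weights(1, 1, 1, 1, 1, 1)
  Mu <- transition_matrix(v, ucfg)
  expect_equal(Mu[i0, match("c1", v$ids)], 1 / 3, tolerance = 1e-12)
  expect_equal(Mu[i0, match("pa", v$ids)], 1 / 6, tolerance = 1e-12)
  expect_equal(Mu[i0, match("f1", v$ids)], 1 / 9, tolerance = 1e-12)
  ib <- match("pb", v$ids)          # pb's only out-neighbor is p0
  expect_equal(unname(Mu[ib, match("p0", v$ids)]), 1)

  # function node with parent and child neighbors: equal higher/lower
  # weights give equal probabilities
  i1 <- match("f1", v$ids)
  w_eq <- edge_weights(1, 1, 1, 1, 2, 2)
  Me <- transition_matrix(v, w_eq)
  expect_equal(Me[i1, match("f2", v$ids)], Me[i1, match("f3", v$ids)])
  # row-stochastic where defined
  rs <- Matrix::rowSums(M)
  expect_true(all(abs(rs[setdiff(seq_along(v$ids), v$sinks)] - 1) < 1e-12))
  expect_true(all(rs[v$sinks] == 0))
})

test_that("unweighted neighbor kinds raise a configuration error", {
  g <- toy_graph()
  v <- directed_view(g, "c1")
  cfg <- edge_weights()
  cfg$weights <- cfg$weights[c("drug", "disease", "protein")]
  expect_error(transition_matrix(v, cfg), "no weight configured")
})

test_that("two-node source/sink walk has the closed-form fixed point", {
  dp <- data.frame(node_1 = "c1", node_1_type = "drug",
                   node_2 = "p1", node_2_type = "protein")
  xp <- data.frame(node_1 = "d1", node_1_type = "disease",
                   node_2 = "p2", node_2_type = "protein")
  ppi <- data.frame(node_1 = "p1", node_1_type = "protein",
                    node_2 = "p2", node_2_type = "protein")
  g2 <- suppressMessages(assemble_graph(dp[1, ], NULL,
          data.frame(node_1 = "p1", node_1_type = "protein",
                     node_2 = "p1", node_2_type = "protein")[0, ]))
  # exact two-node graph: drug c1 -- protein p1
  cfg <- edge_weights(alpha = 0.5, eps = 1e-14)
  v <- directed_view(g2, "c1")
  ex <- exact_profile_oracle(v, cfg)
  expect_equal(unname(ex[c("c1", "p1")]), c(2 / 3, 1 / 3), tolerance = 1e-14)
  pw <- diffusion_profile(g2, cfg, "c1")
  expect_equal(unname(pw[c("c1", "p1")]), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("alpha -> 0 collapses the profile onto the restart vector", {
  g <- toy_graph()
  cfg <- edge_weights(alpha = 1e-9, eps = 1e-13)
  r <- diffusion_profile(g, cfg, "c1")
  s <- as.numeric(names(r) == "c1")
  expect_lt(sum(abs(as.numeric(r) - s)), 1e-6)
})

test_that("power iteration agrees with the dense oracle on random typed graphs", {
  worst <- 0
  for (seed in 1:25) {
    g <- random_typed_graph(seed)
    cfg <- random_weights(seed + 1000)
    focal <- sample(g$nodes$id[g$nodes$kind %in% c("drug", "disease")], 1)
    v <- directed_view(g, focal)
    pw <- diffusion_profile(g, cfg, focal)
    ex <- exact_profile_oracle(v, cfg)
    worst <- max(worst, sum(abs(as.numeric(pw) - as.numeric(ex))))
  }
  expect_lt(worst, 1e-7)
})

test_that("uniform weights reproduce an independent personalized PageRank", {
  set.seed(11)
  n <- 25
  repeat { ig <- igraph::sample_gnp(n, 0.15); if (igraph::is_connected(ig)) break }
  el <- igraph::as_edgelist(ig)
  prot <- sprintf("p%02d", seq_len(n))
  ppi <- data.frame(node_1 = prot[el[, 1]], node_1_type = "protein",
                    node_2 = prot[el[, 2]], node_2_type = "protein")
  dp <- data.frame(node_1 = "c1", node_1_type = "drug",
                   node_2 = prot[1:2], node_2_type = "protein")
  g <- suppressMessages(assemble_graph(dp, NULL, ppi))
  cfg <- edge_weights(1, 1, 1, 1, 1, 1, alpha = 0.85, eps = 1e-13)
  v <- directed_view(g, "c1")
  r <- diffusion_profile(g, cfg, "c1")
  dg <- igraph::make_graph(t(cbind(v$i, v$j)), n = length(v$ids), directed = TRUE)
  s <- as.numeric(seq_along(v$ids) == v$focal_idx)
  pr <- igraph::page_rank(dg, personalized = s, damping = 0.85,
                          algo = "prpack")$vector
  expect_lt(max(abs(as.numeric(r) - pr)), 1e-8)
})

test_that("profiles conserve mass, are nonneg, deterministic and local", {
  g <- default_fixture()$graph
  cfg <- edge_weights()
  r1 <- diffusion_profile(g, cfg, "DR01")
  expect_true(all(r1 >= 0))
  expect_equal(sum(r1), 1, tolerance = 1e-9)
  expect_gt(r1["DR01"], 0)
  options(msinteractome.cache = FALSE)
  on.exit(options(msinteractome.cache = TRUE))
  r2 <- diffusion_profile(g, cfg, "DR01")
  expect_identical(as.numeric(r1), as.numeric(r2))

  # locality: a disconnected protein island is never visited
  tb <- toy_tables()
  tb$ppi <- rbind(tb$ppi, data.frame(node_1 = "p8", node_1_type = "protein",
                                     node_2 = "p9", node_2_type = "protein"))
  gi <- suppressMessages(assemble_graph(tb$drug_protein, tb$disease_protein,
                                        tb$ppi, tb$protein_function, tb$hierarchy))
  ri <- diffusion_profile(gi, cfg, "c1")
  expect_identical(unname(ri[c("p8", "p9")]), c(0, 0))
})

test_that("profiles vary continuously in alpha on the fixture", {
  g <- default_fixture()$graph
  r1 <- diffusion_profile(g, edge_weights(alpha = 0.860), "DR01")
  r2 <- diffusion_profile(g, edge_weights(alpha = 0.861), "DR01")
  expect_lt(sum(abs(as.numeric(r1) - as.numeric(r2))), 0.1)
})

test_that("a uniform restart over two entities is not the mean of the two single-focal profiles", {
  g <- toy_graph()
  cfg <- edge_weights(alpha = 0.7)
  v1 <- directed_view(g, "c1"); v2 <- directed_view(g, "c2")
  s12 <- as.numeric(v1$ids %in% c("c1", "c2")) / 2
  mix <- exact_profile_oracle(v1, cfg, s = s12)
  single <- (as.numeric(exact_profile_oracle(v1, cfg)) +
             as.numeric(exact_profile_oracle(v2, cfg))) / 2
  expect_gt(sum(abs(as.numeric(mix) - single)), 1e-3)
})

test_that("sink mass is redistributed through the restart vector", {
  # c1 -- p1 -- c2: walker reaching the rival drug c2 must restart, so
  # the fixed point solves r_c1 = (1 - a) + a^3 r_c1
  dp2 <- data.frame(node_1 = c("c1", "c2"), node_1_type = "drug",
                    node_2 = c("p1", "p1"), node_2_type = "protein")
  empty_ppi <- data.frame(node_1 = character(0), node_1_type = character(0),
                          node_2 = character(0), node_2_type = character(0))
  g2 <- suppressMessages(assemble_graph(dp2, NULL, empty_ppi))
  a <- 0.5
  cfg <- edge_weights(alpha = a, eps = 1e-13)
  r <- diffusion_profile(g2, cfg, "c1")
  expect_equal(unname(r["c1"]), (1 - a) / (1 - a^3), tolerance = 1e-10)
  expect_equal(unname(r["p1"]), a * (1 - a) / (1 - a^3), tolerance = 1e-10)
})
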