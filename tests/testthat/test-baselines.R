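test_that("protein overlap is the Jaccard index", {
  expect_equal(protein_overlap(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(protein_overlap(c("A", "B"), c("A", "B")), 1)
  expect_equal(protein_overlap(c("A", "B"), c("C", "D")), 0)
  expect_error(protein_overlap(character(0), "A"), "nonempty")
})

test_that("closest distance averages per-target minima on the PPI layer", {
  # path s -- x -- t
  ppi <- data.frame(node_1 = c("s", "x"), node_1_type = "protein",
                    node_2 = c("x", "t"), node_2_type = "protein")
  dp <- data.frame(node_1 = "c1", node_1_type = "drug",
                   node_2 = "t", node_2_type = "protein")
  xp <- data.frame(node_1 = "d1", node_1_type = "disease",
                   node_2 = "s", node_2_type = "protein")
  g <- suppressMessages(assemble_graph(dp, xp, ppi))
  expect_equal(closest_distance(S = "s", T = "t", g), 2)
  expect_equal(closest_distance(S = c("s", "x"), T = "t", g), 1)
  expect_equal(closest_distance(S = "s", T = "s", g), 0)   # target in S
  # unreachable targets are dropped with a warning
  ppi2 <- rbind(ppi, data.frame(node_1 = "u", node_1_type = "protein",
                                node_2 = "v", node_2_type = "protein"))
  g2 <- suppressMessages(assemble_graph(dp, xp, ppi2))
  expect_warning(d <- closest_distance("s", c("t", "u"), g2), "unreachable")
  expect_equal(d, 2)
})

test_that("degree-matched sampling preserves size and degree bins", {
  fix <- default_fixture()
  ppi <- ppi_igraph(fix$graph)
  prot <- fix$graph$nodes$id[fix$graph$nodes$kind == "protein"]
  set.seed(5)
  orig <- sample(prot, 8)
  draws <- degree_matched_sample(orig, ppi, 40, seed = 11, min_bin_size = 10)
  expect_length(draws, 40)
  expect_true(all(lengths(draws) == 8))
  expect_true(all(vapply(draws, anyDuplicated, integer(1)) == 0L))
  # same seed reproduces; mean degree tracks the original within 25%
  draws2 <- degree_matched_sample(orig, ppi, 40, seed = 11, min_bin_size = 10)
  expect_identical(draws, draws2)
  deg <- igraph::degree(ppi)
  md <- mean(vapply(draws, function(s) mean(deg[s]), numeric(1)))
  expect_lt(abs(md - mean(deg[orig])) / mean(deg[orig]), 0.25)
  expect_error(degree_matched_sample(orig, ppi, 5, min_bin_size = 1000),
               "min_bin_size")
})

test_that("proximity z-score is calibrated on null-drawn sets and flags degenerate nulls", {
  fix <- default_fixture()
  ppi <- ppi_igraph(fix$graph)
  prot <- fix$graph$nodes$id[fix$graph$nodes$kind == "protein"]
  set.seed(21)
  zs <- replicate(15, {
    sd1 <- sample.int(1e6, 1); sd2 <- sample.int(1e6, 1)
    S <- degree_matched_sample(sample(prot, 6), ppi, 1, sd1, min_bin_size = 10)[[1]]
    T <- degree_matched_sample(sample(prot, 4), ppi, 1, sd2, min_bin_size = 10)[[1]]
    suppressWarnings(proximity_zscore(S, T, ppi, n_perm = 60,
                                      seed = sample.int(1e6, 1),
                                      min_bin_size = 10))$z
  })
  expect_lt(abs(mean(zs)), 0.3)
  expect_error(proximity_zscore("a", "b", ppi, n_perm = 1), "n_perm")
})

test_that("a molecular-route drug sits closer to its disease module than chance", {
  fix <- default_fixture()
  mol <- names(fix$routes)[fix$routes == "molecular"][1]
  dz <- names(fix$disease_module)[fix$disease_module == fix$drug_module[[mol]]][1]
  S <- protein_set(fix$graph, dz); T <- protein_set(fix$graph, mol)
  z <- suppressWarnings(proximity_zscore(S, T, fix$graph, n_perm = 150,
                                         seed = 2, min_bin_size = 10))
  expect_lt(z$z, -1)
})

test_that("term collections follow the closure, multiset and enrichment definitions", {
  # p1 annotated to leaf fB (ancestor fA), p2 to fB as well, p3 to fC
  dp <- data.frame(node_1 = "c1", node_1_type = "drug",
                   node_2 = "p1", node_2_type = "protein")
  xp <- data.frame(node_1 = "d1", node_1_type = "disease",
                   node_2 = "p3", node_2_type = "protein")
  ppi <- data.frame(node_1 = c("p1", "p2"), node_1_type = "protein",
                    node_2 = c("p2", "p3"), node_2_type = "protein")
  ann <- data.frame(node_1 = c("p1", "p2", "p3"), node_1_type = "protein",
                    node_2 = c("fB", "fB", "fC"), node_2_type = "biological_function")
  hier <- data.frame(node_1 = c("fB", "fC"), node_1_type = "biological_function",
                     node_2 = c("fA", "fA"), node_2_type = "biological_function")
  g <- suppressMessages(assemble_graph(dp, xp, ppi, ann, hier))
  corpus <- annotation_corpus(g)
  expect_setequal(term_sets("p1", corpus, "closure"), c("fA", "fB"))
  expect_setequal(term_sets("p1", corpus, "direct"), "fB")
  ms <- term_sets(c("p1", "p2"), corpus, "multiset")
  expect_equal(ms[["fB"]], 2)
  expect_equal(ms[["fA"]], 2)
  expect_warning(out <- term_sets("zz", corpus, "closure"), "no annotated")
  expect_length(out, 0)
})

test_that("enrichment matches an independent one-sided Fisher test", {
  # 20 background proteins; term fT covers all 5 query proteins but only
  # 2 non-query proteins
  prot <- sprintf("q%02d", 1:20)
  ann <- rbind(
    data.frame(node_1 = prot[1:7], node_2 = "fT"),
    data.frame(node_1 = prot, node_2 = "fBase"))
  ann <- data.frame(node_1 = ann$node_1, node_1_type = "protein",
                    node_2 = ann$node_2, node_2_type = "biological_function")
  hier <- data.frame(node_1 = "fT", node_1_type = "biological_function",
                     node_2 = "fBase", node_2_type = "biological_function")
  dp <- data.frame(node_1 = "c1", node_1_type = "drug",
                   node_2 = prot[1], node_2_type = "protein")
  xp <- data.frame(node_1 = "d1", node_1_type = "disease",
                   node_2 = prot[2], node_2_type = "protein")
  ppi <- data.frame(node_1 = prot[-20], node_1_type = "protein",
                    node_2 = prot[-1], node_2_type = "protein")
  g <- suppressMessages(assemble_graph(dp, xp, ppi, ann, hier))
  corpus <- annotation_corpus(g)
  query <- prot[1:5]
  enr <- term_sets(query, corpus, "enriched")
  expect_true("fT" %in% enr)
  expect_false("fBase" %in% enr)   # covers everything, not enriched
  # oracle: Fisher exact one-sided on the 2x2 table for fT
  ft <- stats::fisher.test(matrix(c(5, 0, 2, 13), 2), alternative = "greater")
  expect_lt(ft$p.value, 0.05)
})

test_that("term overlap handles sets and multisets exactly", {
  U <- c(a = 2, b = 1); V <- c(a = 1, c = 1)
  expect_equal(term_overlap(U, V, "jaccard"), 1 / 4)
  expect_equal(term_overlap(U, V, "intersection"), 1)
  expect_equal(term_overlap(c("x", "y"), c("x", "y"), "jaccard"), 1)
  expect_equal(term_overlap(c("x"), c("y"), "jaccard"), 0)
  expect_warning(v <- term_overlap(character(0), character(0)), "empty")
  expect_true(is.na(v))
})

test_that("semantic similarity follows the information-content definitions", {
  fix <- default_fixture()
  corpus <- annotation_corpus(fix$graph)
  # IC monotone child -> parent over every hierarchy edge
  h <- fix$graph$edges[fix$graph$edges$type ==
                         "biological_function|biological_function", ]
  expect_true(all(corpus$p[h$from] <= corpus$p[h$to] + 1e-12))
  # a term with itself: Resnik = IC of the term
  u <- names(which(corpus$p > 0 & corpus$p < 1))[1]
  expect_equal(semantic_similarity(corpus, u, u, "resnik"),
               -log(corpus$p[[u]]))
  # the root has p = 1 so Resnik through it is 0
  root <- names(which(corpus$p == 1))[1]
  expect_equal(semantic_similarity(corpus, root, root, "resnik"), 0)
  # Resnik bounded by the participants' IC
  set.seed(3)
  terms <- sample(names(corpus$p), 8)
  for (a in terms) for (b in terms) {
    r <- semantic_similarity(corpus, a, b, "resnik")
    expect_lte(r, min(term_ic(corpus, a), term_ic(corpus, b)) + 1e-12)
    s <- semantic_similarity(corpus, a, b, "sim_ic")
    expect_true(is.finite(s))
  }
  # simGIC identity and bounds
  U <- term_sets(protein_set(fix$graph, "DR01"), corpus, "direct")
  expect_equal(sim_gic(corpus, U, U), 1)
  V <- term_sets(protein_set(fix$graph, "DZ01"), corpus, "direct")
  gv <- sim_gic(corpus, U, V)
  expect_gte(gv, 0); expect_lte(gv, 1)
})

test_that("aggregation modes match the average, max and best-match-average formulas", {
  fix <- default_fixture()
  corpus <- annotation_corpus(fix$graph)
  set.seed(8)
  U <- sample(names(corpus$p), 3); V <- sample(names(corpus$p), 2)
  sim <- outer(U, V, Vectorize(function(a, b)
    semantic_similarity(corpus, a, b, "resnik")))
  expect_equal(aggregate_similarity(corpus, U, V, "resnik", "average"),
               mean(sim))
  expect_equal(aggregate_similarity(corpus, U, V, "resnik", "max"), max(sim))
  expect_equal(aggregate_similarity(corpus, U, V, "resnik", "best_match_average"),
               (sum(apply(sim, 1, max)) + sum(apply(sim, 2, max))) /
                 (length(U) + length(V)))
  # max aggregation is permutation invariant
  expect_equal(aggregate_similarity(corpus, rev(U), V, "resnik", "max"),
               aggregate_similarity(corpus, U, rev(V), "resnik", "max"))
  # singleton sets: all three modes coincide
  expect_equal(aggregate_similarity(corpus, U[1], V[1], "resnik", "average"),
               aggregate_similarity(corpus, U[1], V[1], "resnik", "max"))
})

test_that("every functional-overlap baseline yields a finite score on the fixture", {
  fix <- default_fixture()
  corpus <- annotation_corpus(fix$graph)
  T <- protein_set(fix$graph, "DR01")
  S <- protein_set(fix$graph, "DZ01")
  # raw overlap family: {set closure, multiset, enriched} x {jaccard, intersection}
  for (mode in c("closure", "multiset", "enriched"))
    for (type in c("jaccard", "intersection")) {
      v <- suppressWarnings(term_overlap(term_sets(T, corpus, mode),
                                         term_sets(S, corpus, mode), type))
      expect_true(is.finite(v) || mode == "enriched")
    }
  # z-scored family
  for (mode in c("closure", "multiset"))
    for (type in c("jaccard", "intersection")) {
      z <- zscored_term_overlap(S, T, fix$graph, corpus, mode, type,
                                n_perm = 20, seed = 3, min_bin_size = 10)
      expect_true(is.finite(z$z) || z$degenerate)
    }
  # semantic family: Resnik and simIC under three aggregations, plus simGIC
  Ud <- term_sets(T, corpus, "direct"); Vd <- term_sets(S, corpus, "direct")
  for (kind in c("resnik", "sim_ic"))
    for (mode in c("average", "max", "best_match_average"))
      expect_true(is.finite(aggregate_similarity(corpus, Ud, Vd, kind, mode)))
  expect_true(is.finite(sim_gic(corpus, Ud, Vd)))
})

test_that("shared-function pairs score against a degree-matched distance null", {
  fix <- default_fixture()
  corpus <- annotation_corpus(fix$graph)
  # find a directly co-annotated adjacent pair
  e <- fix$graph$edges
  ppe <- e[e$type == "protein|protein", ]
  pair <- NULL
  for (i in seq_len(nrow(ppe))) {
    a <- ppe$from[i]; b <- ppe$to[i]
    if (length(intersect(corpus$annotations[[a]], corpus$annotations[[b]]))) {
      pair <- c(a, b); break
    }
  }
  expect_false(is.null(pair))
  z <- shared_function_distance_zscore(pair, fix$graph, corpus, n_perm = 80,
                                       seed = 4, min_bin_size = 10)
  expect_lt(z$z, 0)    # adjacent pair is closer than a typical random pair
  expect_error(shared_function_distance_zscore(pair, fix$graph, corpus,
                                               n_perm = 0), "n_perm")
  # pairs drawn from the null center near zero
  prot <- fix$graph$nodes$id[fix$graph$nodes$kind == "protein"]
  set.seed(31)
  zs <- replicate(12, {
    pr <- degree_matched_sample(sample(prot, 2), ppi_igraph(fix$graph), 1,
                                sample.int(1e6, 1), min_bin_size = 10)[[1]]
    out <- suppressWarnings(
      shared_function_distance_zscore(pr, fix$graph, corpus, n_perm = 60,
                                      seed = sample.int(1e6, 1),
                                      min_bin_size = 10,
                                      require_shared = FALSE))
    if (is.null(out)) NA_real_ else out$z
  })
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.5)
})
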