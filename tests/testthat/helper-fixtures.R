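# Shared fixtures, built in code. The default synthetic interactome and
# its profiles are memoized so the suite generates them once.

.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_env$fix))
    .fixture_env$fix <- generate_interactome(synthetic_spec())
  .fixture_env$fix
}

default_profiles <- function() {
  if (is.null(.fixture_env$profiles)) {
    fix <- default_fixture()
    ents <- c(sort(unique(fix$dataset$drug)), sort(unique(fix$dataset$disease)))
    .fixture_env$profiles <- compute_profiles(fix$graph, edge_weights(), ents)
  }
  .fixture_env$profiles
}

# Hand-built miniature graph: 2 drugs, 2 diseases, 4 proteins, 3
# functions (fB and fC children of fA).
toy_tables <- function() {
  list(
    drug_protein = data.frame(
      node_1 = c("c1", "c1", "c2"), node_1_type = "drug",
      node_2 = c("p1", "p2", "p3"), node_2_type = "protein"),
    disease_protein = data.frame(
      node_1 = c("d1", "d2"), node_1_type = "disease",
      node_2 = c("p3", "p4"), node_2_type = "protein"),
    ppi = data.frame(
      node_1 = c("p1", "p2", "p3"), node_1_type = "protein",
      node_2 = c("p2", "p3", "p4"), node_2_type = "protein"),
    protein_function = data.frame(
      node_1 = c("p2", "p4"), node_1_type = "protein",
      node_2 = c("fB", "fC"), node_2_type = "biological_function"),
    hierarchy = data.frame(
      node_1 = c("fB", "fC"), node_1_type = "biological_function",
      node_2 = c("fA", "fA"), node_2_type = "biological_function"))
}

toy_graph <- function() {
  tb <- toy_tables()
  suppressMessages(assemble_graph(tb$drug_protein, tb$disease_protein, tb$ppi,
                                  tb$protein_function, tb$hierarchy))
}

# Random small typed graph for property tests: a connected random
# protein layer, a random function tree, and randomly attached drugs,
# diseases and annotations.
random_typed_graph <- function(seed, n_prot = 30L, n_drug = 3L, n_dis = 2L,
                               n_fun = 8L, p_edge = 0.12) {
  set.seed(seed)
  prot <- sprintf("p%03d", seq_len(n_prot))
  pair <- combn(prot, 2L)
  take <- runif(ncol(pair)) < p_edge
  ppi <- data.frame(node_1 = c(pair[1, take], prot[-n_prot]),
                    node_2 = c(pair[2, take], prot[-1]))  # path keeps it connected
  ppi <- unique(ppi)
  ppi <- data.frame(node_1 = ppi$node_1, node_1_type = "protein",
                    node_2 = ppi$node_2, node_2_type = "protein")
  fun <- sprintf("f%02d", seq_len(n_fun))
  hier <- data.frame(node_1 = fun[-1],
                     node_2 = fun[pmax(1L, (seq_len(n_fun)[-1]) %/% 2L)])
  hier <- data.frame(node_1 = hier$node_1, node_1_type = "biological_function",
                     node_2 = hier$node_2, node_2_type = "biological_function")
  ann <- data.frame(node_1 = sample(prot, 2L * n_fun, replace = TRUE),
                    node_2 = sample(fun, 2L * n_fun, replace = TRUE))
  ann <- unique(ann)
  ann <- data.frame(node_1 = ann$node_1, node_1_type = "protein",
                    node_2 = ann$node_2, node_2_type = "biological_function")
  dp <- do.call(rbind, lapply(sprintf("c%02d", seq_len(n_drug)), function(d)
    data.frame(node_1 = d, node_1_type = "drug",
               node_2 = sample(prot, 2L), node_2_type = "protein")))
  xp <- do.call(rbind, lapply(sprintf("d%02d", seq_len(n_dis)), function(d)
    data.frame(node_1 = d, node_1_type = "disease",
               node_2 = sample(prot, 3L), node_2_type = "protein")))
  suppressMessages(assemble_graph(dp, xp, ppi, ann, hier))
}

random_weights <- function(seed) {
  set.seed(seed)
  w <- runif(6, 1, 9)
  edge_weights(w[1], w[2], w[3], w[4], w[5], w[6],
               alpha = runif(1, 0.5, 0.95), eps = 1e-10)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
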