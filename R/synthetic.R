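#' Specification for a synthetic multiscale interactome
#'
#' Describes a miniature interactome with planted treatment structure:
#' a modular protein-protein network (stochastic block wiring with
#' power-law degree heterogeneity inside blocks), one function subtree
#' per module under a common root, diseases attached to module proteins,
#' and drugs acting through one of two planted routes. A *molecular*
#' drug targets proteins inside its disease's protein set. A
#' *functional* drug targets satellite proteins that are far from the
#' disease module in the protein-protein network but annotated to the
#' same function subtree, so its treatments are only recoverable when
#' function nodes are present.
#'
#' @param n_modules number of protein modules (each hosts diseases,
#'   drugs and a function subtree).
#' @param proteins_per_module proteins per module, including
#'   `n_satellites` satellite proteins.
#' @param n_satellites satellite proteins per module; satellites of
#'   module m are annotated to the previous module's function subtree
#'   and attach to the protein network only sparsely.
#' @param n_drugs,n_diseases entity counts (assigned to modules
#'   cyclically).
#' @param functions_per_module nodes of each module's function tree
#'   (heap-ordered; node k is a child of node floor(k/2)).
#' @param hierarchy_depth implied depth of the default 7-node tree;
#'   retained for reporting.
#' @param p_in,p_out within/between-module protein edge probabilities
#'   (must satisfy `p_in > p_out`).
#' @param functional_route_fraction fraction of drugs using the
#'   functional route.
#' @param targets_per_drug protein targets per drug.
#' @param proteins_per_disease disease-associated proteins per disease.
#' @param pgx_rate fraction of approved pairs receiving a planted
#'   treatment-altering gene.
#' @param signature_noise_sd noise added to profile-derived expression
#'   signatures.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modules = 4L, proteins_per_module = 25L,
                           n_satellites = 5L, n_drugs = 20L, n_diseases = 8L,
                           functions_per_module = 7L, hierarchy_depth = 3L,
                           p_in = 0.15, p_out = 0.01,
                           functional_route_fraction = 0.5,
                           targets_per_drug = 3L, proteins_per_disease = 8L,
                           pgx_rate = 1, signature_noise_sd = 0.5,
                           seed = 0L) {
  stopifnot(p_in > p_out, n_modules >= 1L, proteins_per_module > n_satellites,
            n_drugs >= 1L, n_diseases >= 1L, functions_per_module >= 3L,
            targets_per_drug >= 1L, targets_per_drug <= n_satellites,
            proteins_per_disease <= proteins_per_module - n_satellites,
            functional_route_fraction >= 0, functional_route_fraction <= 1,
            pgx_rate >= 0, pgx_rate <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic interactome with planted treatment structure
#'
#' @param spec a [synthetic_spec()].
#' @param signatures also emit profile-derived expression signatures
#'   (computes drug diffusion profiles with the default weights).
#' @return list of class `synthetic_interactome` with elements `graph`
#'   (an `msgraph`), `dataset` (a `treatment_dataset`), `pgx`
#'   (`pgx_triplets`), `signatures` (named list or NULL), `routes`
#'   (named character per drug), `drug_module`, `disease_module`, and
#'   the `spec`.
#' @export
generate_interactome <- function(spec, signatures = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fix <- .with_seed(spec$seed, .generate_impl(spec))
  if (signatures) {
    profiles <- compute_profiles(fix$graph, edge_weights(),
                                 names(fix$routes))
    fix$signatures <- .with_seed(spec$seed + 1L,
                                 .make_signatures(fix, profiles, spec))
  }
  fix
}

.generate_impl <- function(spec) {
  nm <- spec$n_modules; ppm <- spec$proteins_per_module
  nsat <- spec$n_satellites
  prot <- outer(seq_len(nm), seq_len(ppm),
                function(m, i) sprintf("P%02d_%02d", m, i))
  module_of <- rep(seq_len(nm), times = ppm)
  prot <- as.vector(prot); names(module_of) <- prot
  is_sat <- rep(seq_len(ppm) > (ppm - nsat), each = nm)
  # reorder into module blocks
  o <- order(module_of, prot)
  prot <- prot[o]; module_of <- module_of[o]; is_sat <- is_sat[o]
  names(is_sat) <- prot
  core <- split(prot[!is_sat], module_of[!is_sat])
  sats <- split(prot[is_sat], module_of[is_sat])
  prev_m <- function(m) ((m - 2L) %% nm) + 1L
  next_m <- function(m) (m %% nm) + 1L

  # --- protein-protein layer: SBM over core proteins with power-law
  # degree propensities; satellites attach sparsely to the next module.
  core_ids <- unlist(core, use.names = FALSE)
  ncore <- length(core_ids)
  theta <- pmin(stats::runif(ncore)^(-1 / 1.5), 8)
  theta <- theta / mean(theta)
  names(theta) <- core_ids
  pair <- utils::combn(core_ids, 2L)
  same <- module_of[pair[1, ]] == module_of[pair[2, ]]
  base <- ifelse(same, spec$p_in, spec$p_out)
  pr <- pmin(1, base * theta[pair[1, ]] * theta[pair[2, ]])
  take <- stats::runif(length(pr)) < pr
  ppi <- data.frame(node_1 = pair[1, take], node_2 = pair[2, take])
  # spanning path per module + a ring across modules keeps the layer connected
  for (m in seq_len(nm)) {
    cs <- core[[m]]
    ppi <- rbind(ppi, data.frame(node_1 = cs[-length(cs)], node_2 = cs[-1]))
    ppi <- rbind(ppi, data.frame(node_1 = cs[1], node_2 = core[[next_m(m)]][1]))
  }
  # satellites of module m: two sparse edges into module m's core
  for (m in seq_len(nm)) for (s in sats[[m]]) {
    nb <- sample(core[[m]], 2L)
    ppi <- rbind(ppi, data.frame(node_1 = s, node_2 = nb))
  }
  ppi <- unique(data.frame(node_1 = pmin(ppi$node_1, ppi$node_2),
                           node_2 = pmax(ppi$node_1, ppi$node_2)))
  ppi <- ppi[ppi$node_1 != ppi$node_2, ]
  ppi <- data.frame(node_1 = ppi$node_1, node_1_type = "protein",
                    node_2 = ppi$node_2, node_2_type = "protein")

  # --- function hierarchy: a heap-ordered tree per module under a root
  nf <- spec$functions_per_module
  fun <- lapply(seq_len(nm), function(m) sprintf("F%02d_%02d", m, seq_len(nf)))
  hier <- data.frame(node_1 = character(0), node_2 = character(0))
  for (m in seq_len(nm)) {
    f <- fun[[m]]
    ch <- seq_len(nf)[-1]
    hier <- rbind(hier, data.frame(node_1 = f[ch], node_2 = f[ch %/% 2L]))
    hier <- rbind(hier, data.frame(node_1 = f[1], node_2 = "F_ROOT"))
  }
  hier <- data.frame(node_1 = hier$node_1, node_1_type = "biological_function",
                     node_2 = hier$node_2, node_2_type = "biological_function")
  leaves <- lapply(fun, function(f) {
    k <- seq_along(f)
    f[!(k %in% (k %/% 2L))]
  })

  # --- annotations: core proteins -> own module's leaves;
  # satellites of module m -> previous module's leaves
  ann <- list()
  for (m in seq_len(nm)) {
    for (p in core[[m]]) {
      ls <- sample(leaves[[m]], sample(1:2, 1))
      ann[[length(ann) + 1L]] <- data.frame(node_1 = p, node_2 = ls)
    }
    for (s in sats[[m]]) {
      ls <- sample(leaves[[prev_m(m)]], 2L)
      ann[[length(ann) + 1L]] <- data.frame(node_1 = s, node_2 = ls)
    }
  }
  ann <- do.call(rbind, ann)
  ann <- data.frame(node_1 = ann$node_1, node_1_type = "protein",
                    node_2 = ann$node_2, node_2_type = "biological_function")

  # --- diseases
  dz_ids <- sprintf("DZ%02d", seq_len(spec$n_diseases))
  dz_mod <- stats::setNames(rep_len(seq_len(nm), spec$n_diseases), dz_ids)
  dz_prot <- lapply(dz_ids, function(d)
    sample(core[[dz_mod[[d]]]], spec$proteins_per_disease))
  names(dz_prot) <- dz_ids
  disease_protein <- do.call(rbind, lapply(dz_ids, function(d)
    data.frame(node_1 = d, node_1_type = "disease",
               node_2 = dz_prot[[d]], node_2_type = "protein")))

  # --- drugs: molecular route targets disease proteins of the module;
  # functional route targets the satellites annotated to the module's
  # subtree (which live attached to the next module's protein block)
  dr_ids <- sprintf("DR%02d", seq_len(spec$n_drugs))
  dr_mod <- stats::setNames(rep_len(seq_len(nm), spec$n_drugs), dr_ids)
  n_func <- round(spec$functional_route_fraction * spec$n_drugs)
  routes <- stats::setNames(
    sample(rep(c("functional", "molecular"),
               c(n_func, spec$n_drugs - n_func))), dr_ids)
  dr_targets <- lapply(dr_ids, function(dr) {
    m <- dr_mod[[dr]]
    if (routes[[dr]] == "functional") {
      sample(sats[[next_m(m)]], spec$targets_per_drug)
    } else {
      pool <- unique(unlist(dz_prot[dz_ids[dz_mod == m]]))
      sample(pool, min(spec$targets_per_drug, length(pool)))
    }
  })
  names(dr_targets) <- dr_ids
  drug_protein <- do.call(rbind, lapply(dr_ids, function(dr)
    data.frame(node_1 = dr, node_1_type = "drug",
               node_2 = dr_targets[[dr]], node_2_type = "protein")))

  graph <- suppressMessages(assemble_graph(
    drug_protein = drug_protein, disease_protein = disease_protein,
    ppi = ppi, protein_function = ann, hierarchy = hier))

  pairs <- do.call(rbind, lapply(dr_ids, function(dr) {
    dzs <- dz_ids[dz_mod == dr_mod[[dr]]]
    if (!length(dzs)) return(NULL)
    data.frame(drug = dr, disease = dzs)
  }))
  dataset <- treatment_dataset(pairs, graph)

  # planted treatment-altering genes: a target of the drug, i.e. a
  # high-visitation protein in both profiles of the pair
  n_pgx <- round(spec$pgx_rate * nrow(dataset))
  pgx_rows <- if (n_pgx > 0) {
    pick <- sort(sample(nrow(dataset), n_pgx))
    data.frame(drug = dataset$drug[pick], disease = dataset$disease[pick],
               gene = vapply(dataset$drug[pick], function(dr)
                 sample(dr_targets[[dr]], 1L), character(1)))
  } else data.frame(drug = character(0), disease = character(0),
                    gene = character(0))
  pgx <- pgx_triplets(pgx_rows, dataset, graph)

  structure(list(graph = graph, dataset = dataset, pgx = pgx,
                 signatures = NULL, routes = routes,
                 drug_module = dr_mod, disease_module = dz_mod,
                 drug_targets = dr_targets, disease_proteins = dz_prot,
                 spec = spec),
            class = "synthetic_interactome")
}

.make_signatures <- function(fix, profiles, spec) {
  prot <- fix$graph$nodes$id[fix$graph$nodes$kind == "protein"]
  sigs <- lapply(names(fix$routes), function(dr) {
    base <- scale(rank(profiles[prot, dr]))[, 1]
    expression_signature(dr, prot,
                         base + stats::rnorm(length(prot),
                                             sd = spec$signature_noise_sd),
                         cell_line = "SYN1", dose = "10uM", time = "24h")
  })
  stats::setNames(sigs, names(fix$routes))
}

#' Write a synthetic interactome to fixture files
#'
#' Emits the five edge-table TSVs ([write_edge_tables()]), `pairs.tsv`
#' (`drug`, `disease`), `pgx.tsv` (`drug`, `disease`, `gene`) and, when
#' present, per-drug signature TSVs (`gene`, `z`) with a
#' `signature_metadata.tsv` sidecar, so the loaders are exercised
#' end-to-end.
#'
#' @param fix a `synthetic_interactome`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_tables(fix$graph, dir)
  utils::write.table(fix$dataset, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fix$pgx, file.path(dir, "pgx.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fix$signatures)) {
    sd <- file.path(dir, "signatures")
    dir.create(sd, showWarnings = FALSE)
    meta <- do.call(rbind, lapply(names(fix$signatures), function(dr) {
      sig <- fix$signatures[[dr]]
      f <- paste0(dr, ".tsv")
      utils::write.table(as.data.frame(sig), file.path(sd, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      data.frame(drug = dr, cell_line = attr(sig, "cell_line"),
                 dose = attr(sig, "dose"), time = attr(sig, "time"), file = f)
    }))
    utils::write.table(meta, file.path(dir, "signature_metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a fixture directory written by [write_fixture()]
#' @param dir fixture directory.
#' @return a list with `graph`, `dataset`, `pgx`, `signatures`.
#' @export
read_fixture <- function(dir) {
  graph <- read_edge_tables(dir)
  dataset <- treatment_dataset(file.path(dir, "pairs.tsv"), graph)
  pgx_path <- file.path(dir, "pgx.tsv")
  pgx <- if (file.exists(pgx_path) &&
             nrow(utils::read.delim(pgx_path)) > 0)
    pgx_triplets(pgx_path, dataset, graph) else NULL
  sigs <- NULL
  meta_path <- file.path(dir, "signature_metadata.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, colClasses = "character")
    sigs <- lapply(seq_len(nrow(meta)), function(i) {
      tab <- utils::read.delim(file.path(dir, "signatures", meta$file[i]))
      expression_signature(meta$drug[i], tab$gene, tab$z,
                           cell_line = meta$cell_line[i], dose = meta$dose[i],
                           time = meta$time[i])
    })
    names(sigs) <- meta$drug
  }
  list(graph = graph, dataset = dataset, pgx = pgx, signatures = sigs)
}
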