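#' Treatment-explanation subgraph from two diffusion profiles
#'
#' Takes the k most visited nodes of the drug profile and of the disease
#' profile (ties broken by node id), always including the two focal
#' nodes, induces the subgraph on their union and removes isolated
#' nodes. The retained nodes' share of total visitation mass in each
#' profile is reported alongside.
#'
#' @param rc,rd drug and disease `diffusion_profile`s over `graph`.
#' @param graph the `msgraph` the profiles were computed on.
#' @param k number of top nodes per profile (default 10, the case-study
#'   setting); clipped to the node count with a warning.
#' @return list of class `explanation_subgraph` with the igraph
#'   `subgraph` (node attributes `kind`, `rc`, `rd`), the retained
#'   `nodes`, and `mass_share` (named: rc, rd).
#' @export
top_k_subgraph <- function(rc, rd, graph, k = 10L) {
  n <- nrow(graph$nodes)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) { warning("k exceeds node count; clipped"); k <- n }
  top_of <- function(r) names(r)[order(-as.numeric(r), names(r))][seq_len(k)]
  keep <- unique(c(attr(rc, "focal"), attr(rd, "focal"), top_of(rc), top_of(rd)))
  e <- graph$edges
  ein <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ein[c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = keep))
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  nodes <- igraph::V(g)$name
  igraph::V(g)$kind <- node_kind(graph, nodes)
  igraph::V(g)$rc <- as.numeric(rc[nodes])
  igraph::V(g)$rd <- as.numeric(rd[nodes])
  structure(list(subgraph = g, nodes = nodes, k = k,
                 mass_share = c(rc = sum(rc[nodes]), rd = sum(rd[nodes]))),
            class = "explanation_subgraph")
}

#' @export
print.explanation_subgraph <- function(x, ...) {
  cat("Explanation subgraph (k =", x$k, "):", length(x$nodes), "nodes,",
      igraph::ecount(x$subgraph), "edges\n")
  cat("visitation mass covered: drug", round(x$mass_share["rc"], 3),
      "/ disease", round(x$mass_share["rd"], 3), "\n")
  invisible(x)
}

#' Export an explanation subgraph as GraphML
#' @param subgraph an `explanation_subgraph`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_subgraph_graphml <- function(subgraph, path) {
  igraph::write_graph(subgraph$subgraph, path, format = "graphml")
  invisible(path)
}

# Mid-rank percentile in [0, 1]: fraction of strictly smaller values
# plus half the other ties, over n - 1.
.percentile <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Treatment importance of genes for a drug-disease pair
#'
#' `TI(i | c, d) = rc[i] * rd[i]`, the product of the gene's protein
#' visitation frequencies in the drug and disease profiles, with a
#' mid-rank percentile over all protein nodes of the same pair.
#'
#' @param rc,rd drug and disease profiles over the same graph.
#' @param graph the `msgraph` (supplies the protein node set).
#' @param genes optional subset of protein ids to report (default all).
#' @return data.frame (`gene`, `ti`, `percentile`) with the drug and
#'   disease ids as attributes.
#' @export
treatment_importance <- function(rc, rd, graph, genes = NULL) {
  prot <- graph$nodes$id[graph$nodes$kind == "protein"]
  ti <- as.numeric(rc[prot]) * as.numeric(rd[prot])
  out <- data.frame(gene = prot, ti = ti, percentile = .percentile(ti))
  if (!is.null(genes)) {
    miss <- setdiff(genes, prot)
    if (length(miss)) stop("gene(s) not protein nodes: ",
                           paste(miss, collapse = ", "))
    out <- out[match(genes, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "drug") <- attr(rc, "focal")
  attr(out, "disease") <- attr(rd, "focal")
  out
}

# TI for (drug, disease, gene) rows against a profile matrix.
.triplet_ti <- function(triplets, profiles) {
  vapply(seq_len(nrow(triplets)), function(i)
    profiles[triplets$gene[i], triplets$drug[i]] *
      profiles[triplets$gene[i], triplets$disease[i]], numeric(1))
}

#' Sample negative (drug, disease, gene) triplets
#'
#' Draws `n` triplets uniformly at random whose (drug, disease) is an
#' approved pair and whose full triplet is not among the known
#' treatment-altering positives.
#'
#' @param dataset a `treatment_dataset`.
#' @param positives a `pgx_triplets` table.
#' @param graph the `msgraph` (gene pool = all protein nodes).
#' @param n number of negatives.
#' @param seed RNG seed.
#' @return data.frame (`drug`, `disease`, `gene`).
#' @export
sample_negative_triplets <- function(dataset, positives, graph, n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  genes <- graph$nodes$id[graph$nodes$kind == "protein"]
  total <- nrow(dataset) * length(genes) - nrow(positives)
  if (total < n) stop("insufficient non-positive triplets to sample from")
  poskey <- paste(positives$drug, positives$disease, positives$gene)
  .with_seed(seed, {
    out <- data.frame(drug = character(0), disease = character(0),
                      gene = character(0))
    while (nrow(out) < n) {
      m <- (n - nrow(out)) * 2L + 10L
      pi <- sample(nrow(dataset), m, replace = TRUE)
      cand <- data.frame(drug = dataset$drug[pi], disease = dataset$disease[pi],
                         gene = sample(genes, m, replace = TRUE))
      cand <- cand[!(paste(cand$drug, cand$disease, cand$gene) %in% poskey), ,
                   drop = FALSE]
      out <- unique(rbind(out, cand))
    }
    out <- out[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Classify treatment-altering genes by treatment importance
#'
#' Scores positive and negative (drug, disease, gene) triplets by
#' `TI = rc[gene] * rd[gene]` and reports AUROC and average precision of
#' separating the two classes.
#'
#' @param positives,negatives triplet data.frames (`drug`, `disease`,
#'   `gene`).
#' @param profiles profile matrix covering all referenced entities.
#' @return list with `auroc`, `average_precision`, `n_pos`, `n_neg`.
#' @export
classify_treatment_altering <- function(positives, negatives, profiles) {
  if (!nrow(positives) || !nrow(negatives)) stop("both classes must be nonempty")
  if (nrow(positives) != nrow(negatives))
    warning("positive and negative sets differ in size")
  sc <- c(.triplet_ti(positives, profiles), .triplet_ti(negatives, profiles))
  lab <- rep(c(TRUE, FALSE), c(nrow(positives), nrow(negatives)))
  ids <- c(paste(positives$drug, positives$disease, positives$gene),
           paste(negatives$drug, negatives$disease, negatives$gene))
  list(auroc = auroc(sc, lab),
       average_precision = average_precision(sc, lab, ids),
       n_pos = nrow(positives), n_neg = nrow(negatives))
}

#' Build (disease, altered drug, unaltered drug) triplets for a gene set
#'
#' For each (gene, disease), drugs whose treatment the gene is known to
#' alter are crossed with the disease's other approved drugs that the
#' gene is not known to alter.
#'
#' @param positives a `pgx_triplets` table.
#' @param dataset a `treatment_dataset`.
#' @return data.frame (`gene`, `disease`, `drug_altered`,
#'   `drug_unaltered`).
#' @export
build_alteration_triplets <- function(positives, dataset) {
  rows <- list()
  for (g in unique(positives$gene)) {
    pg <- positives[positives$gene == g, , drop = FALSE]
    for (dz in unique(pg$disease)) {
      altered <- unique(pg$drug[pg$disease == dz])
      approved <- unique(dataset$drug[dataset$disease == dz])
      unaltered <- setdiff(approved, altered)
      if (!length(unaltered)) next
      rows[[length(rows) + 1L]] <-
        expand.grid(gene = g, disease = dz, drug_altered = altered,
                    drug_unaltered = unaltered, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), disease = character(0),
                      drug_altered = character(0), drug_unaltered = character(0)))
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Fraction of triplets where the altered drug has higher importance
#'
#' For each gene, the fraction of (disease, altered drug, unaltered
#' drug) triplets with strictly greater treatment importance under the
#' altered drug (ties count as failures). Genes with fewer than
#' `min_triplets` triplets are excluded from the per-gene table. Both
#' aggregations are reported: the mean over qualifying genes and the
#' pooled fraction over all triplets.
#'
#' @param triplets data.frame from [build_alteration_triplets()].
#' @param profiles profile matrix covering all referenced entities.
#' @param min_triplets per-gene triplet floor (default 100).
#' @return list with `per_gene` (data.frame `gene`, `n_triplets`,
#'   `fraction`), `over_genes`, `over_triplets`.
#' @export
altered_fraction <- function(triplets, profiles, min_triplets = 100L) {
  if (!nrow(triplets)) stop("no alteration triplets supplied")
  ti_alt <- .triplet_ti(data.frame(drug = triplets$drug_altered,
                                   disease = triplets$disease,
                                   gene = triplets$gene), profiles)
  ti_un <- .triplet_ti(data.frame(drug = triplets$drug_unaltered,
                                  disease = triplets$disease,
                                  gene = triplets$gene), profiles)
  win <- ti_alt > ti_un
  per <- do.call(rbind, lapply(split(win, triplets$gene), function(w)
    data.frame(n_triplets = length(w), fraction = mean(w))))
  per <- data.frame(gene = rownames(per), per, row.names = NULL)
  keep <- per[per$n_triplets >= min_triplets, , drop = FALSE]
  list(per_gene = keep,
       over_genes = if (nrow(keep)) mean(keep$fraction) else NA_real_,
       over_triplets = mean(win))
}

#' Construct a drug gene-expression signature
#'
#' @param drug drug id.
#' @param genes gene ids (unique).
#' @param z per-gene z-scored expression changes.
#' @param cell_line,dose,time signature metadata; only signatures with
#'   identical metadata are comparable.
#' @return data.frame (`gene`, `z`) of class `expression_signature`.
#' @export
expression_signature <- function(drug, genes, z, cell_line = "cellA",
                                 dose = "10uM", time = "24h") {
  if (anyDuplicated(genes)) stop("gene ids must be unique")
  if (length(genes) < 50L)
    stop("signature needs >= 50 genes for top/bottom-25 extraction")
  structure(data.frame(gene = genes, z = z),
            drug = drug, cell_line = cell_line, dose = dose, time = time,
            class = c("expression_signature", "data.frame"))
}

.sig_meta <- function(sig) {
  c(cell_line = attr(sig, "cell_line"), dose = attr(sig, "dose"),
    time = attr(sig, "time"))
}

#' Overlap similarity of two expression signatures
#'
#' Mean Jaccard overlap of the 25 most upregulated and the 25 most
#' downregulated gene sets of the two signatures.
#' @param sig1,sig2 `expression_signature`s with identical metadata.
#' @param n_top genes per direction (default 25).
#' @return similarity in [0, 1].
#' @export
signature_similarity <- function(sig1, sig2, n_top = 25L) {
  if (!identical(.sig_meta(sig1), .sig_meta(sig2)))
    stop("signatures have incomparable metadata")
  pick <- function(sig, decreasing) {
    o <- order(sig$z, sig$gene, decreasing = decreasing)
    sig$gene[o][seq_len(n_top)]
  }
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  (jac(pick(sig1, TRUE), pick(sig2, TRUE)) +
      jac(pick(sig1, FALSE), pick(sig2, FALSE))) / 2
}

#' Concordance of profile similarity with expression-signature similarity
#'
#' For every pair of drugs with comparable signatures, the similarity of
#' their rank-transformed diffusion profiles (negated Canberra distance)
#' is compared to their expression-signature overlap; the association is
#' summarized by the Spearman correlation.
#'
#' @param profiles profile matrix with a column per drug.
#' @param signatures named list of `expression_signature`s (names =
#'   drug ids).
#' @return list with `rho`, `p_value`, `n_pairs`, and the pairwise table.
#' @export
profile_expression_concordance <- function(profiles, signatures) {
  drugs <- intersect(names(signatures), colnames(profiles))
  if (length(drugs) < 3L) stop("need signatures and profiles for >= 3 drugs")
  rk <- apply(profiles[, drugs, drop = FALSE], 2, rank)
  rows <- list()
  for (i in seq_along(drugs)) for (j in seq_len(i - 1L)) {
    a <- drugs[i]; b <- drugs[j]
    if (!identical(.sig_meta(signatures[[a]]), .sig_meta(signatures[[b]])))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      drug1 = a, drug2 = b,
      profile_sim = profile_similarity(rk[, a], rk[, b], "canberra"),
      signature_sim = signature_similarity(signatures[[a]], signatures[[b]]))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3L) stop("fewer than 3 comparable drug pairs")
  ct <- suppressWarnings(stats::cor.test(tab$profile_sim, tab$signature_sim,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(tab),
       pairs = tab)
}
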