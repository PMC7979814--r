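#' Annotation corpus over the function hierarchy
#'
#' Collects the direct protein -> function annotations of a graph
#' together with the hierarchy DAG, and precomputes for every term `u`
#' the fraction `p(u)` of annotated proteins associated with `u` or any
#' of its descendants. `p` is monotone non-decreasing from child to
#' parent and equals 1 at a root ancestral to all used terms.
#' Information content is `IC(u) = -log p(u)` (natural log; the base
#' rescales Resnik values and cancels in the simIC/simGIC ratios).
#'
#' @param graph an `msgraph` containing protein-function and
#'   function-function layers.
#' @return object of class `annotation_corpus` with elements
#'   `annotations` (named list protein -> direct terms), `ancestors`
#'   (named list term -> ancestors including the term itself), `p`
#'   (named numeric), `n_proteins` (annotated-protein count).
#' @export
annotation_corpus <- function(graph) {
  ann <- .annotation_edges(graph)
  if (!nrow(ann)) stop("graph has no protein-function annotations")
  is_fun <- node_kind(graph, ann$from) == "biological_function"
  fun <- ifelse(is_fun, ann$from, ann$to)
  pro <- ifelse(is_fun, ann$to, ann$from)
  annotations <- split(fun, pro)

  hg <- .hierarchy_igraph(graph)
  if (!igraph::is_dag(hg)) stop("function hierarchy contains a cycle")
  terms <- igraph::V(hg)$name
  ancestors <- lapply(stats::setNames(terms, terms), function(u)
    names(igraph::subcomponent(hg, u, mode = "out")))

  counts <- stats::setNames(numeric(length(terms)), terms)
  for (p in names(annotations)) {
    closure <- unique(unlist(ancestors[annotations[[p]]]))
    counts[closure] <- counts[closure] + 1
  }
  structure(list(annotations = annotations, ancestors = ancestors,
                 p = counts / length(annotations),
                 n_proteins = length(annotations)),
            class = "annotation_corpus")
}

#' Information content of a term
#' @param corpus an `annotation_corpus`.
#' @param u term id(s).
#' @return `-log p(u)` (natural log); `Inf` for terms with no annotation.
#' @export
term_ic <- function(corpus, u) {
  p <- corpus$p[u]
  if (anyNA(p)) stop("term(s) not in corpus: ",
                     paste(u[is.na(p)], collapse = ", "))
  unname(-log(p))
}

# Most informative common ancestor of u and v (terms count as their own
# ancestors). Returns NA when no common ancestor exists.
.mica <- function(corpus, u, v) {
  common <- intersect(corpus$ancestors[[u]], corpus$ancestors[[v]])
  common <- common[corpus$p[common] > 0]
  if (!length(common)) return(NA_character_)
  common[which.max(term_ic(corpus, common))]
}

#' Pairwise semantic similarity between two terms
#'
#' `resnik` is the information content of the most informative common
#' ancestor (MICA); `sim_ic` additionally weights by the structural term
#' `1 - 1/(1 + IC(MICA))` and normalizes by the mean IC of the two
#' terms. Terms with no common ancestor have similarity 0.
#'
#' @param corpus an `annotation_corpus`.
#' @param u,v term ids.
#' @param kind `"resnik"` or `"sim_ic"`.
#' @return a single numeric similarity.
#' @export
semantic_similarity <- function(corpus, u, v, kind = c("resnik", "sim_ic")) {
  kind <- match.arg(kind)
  m <- .mica(corpus, u, v)
  if (is.na(m)) return(0)
  ic_m <- term_ic(corpus, m)
  if (kind == "resnik") return(ic_m)
  denom <- log(corpus$p[[u]]) + log(corpus$p[[v]])
  if (denom == 0) return(0)                      # both terms are roots
  (2 * log(corpus$p[[m]]) / denom) * (1 - 1 / (1 + ic_m))
}

#' Graph information-content similarity of two term sets
#'
#' `simGIC(U, V)` is the IC-weighted Jaccard index of the ancestor
#' closures `A(U)` and `A(V)` (terms plus all their ancestors).
#' @param corpus an `annotation_corpus`.
#' @param U,V character vectors of term ids.
#' @return similarity in [0, 1].
#' @export
sim_gic <- function(corpus, U, V) {
  if (!length(U) || !length(V)) stop("simGIC needs nonempty term sets")
  AU <- unique(unlist(corpus$ancestors[U]))
  AV <- unique(unlist(corpus$ancestors[V]))
  both <- intersect(AU, AV); either <- union(AU, AV)
  ic <- function(x) { v <- term_ic(corpus, x); sum(v[is.finite(v)]) }
  if (!length(either)) return(0)
  denom <- ic(either)
  if (denom == 0) return(1)                      # only roots involved
  ic(both) / denom
}

#' Aggregate pairwise term similarities across two sets
#'
#' @param corpus an `annotation_corpus`.
#' @param U,V nonempty character vectors of term ids.
#' @param kind pairwise similarity passed to [semantic_similarity()].
#' @param mode `"average"` (mean over all pairs), `"max"`, or
#'   `"best_match_average"` (mean of row-wise and column-wise maxima,
#'   weighted by set sizes).
#' @return a single numeric aggregate.
#' @export
aggregate_similarity <- function(corpus, U, V, kind = "resnik",
                                 mode = c("average", "max", "best_match_average")) {
  mode <- match.arg(mode)
  if (!length(U) || !length(V)) stop("aggregate similarity needs nonempty sets")
  sim <- outer(U, V, Vectorize(function(u, v)
    semantic_similarity(corpus, u, v, kind)))
  switch(mode,
    average = mean(sim),
    max = max(sim),
    best_match_average =
      (sum(apply(sim, 1, max)) + sum(apply(sim, 2, max))) /
      (length(U) + length(V)))
}

#' Function term collections for a protein set
#'
#' @param proteins character vector of protein ids.
#' @param corpus an `annotation_corpus`.
#' @param mode `"closure"` (terms annotated directly or through
#'   descendants; a set), `"direct"` (directly annotated terms only),
#'   `"multiset"` (per-term counts of contributing proteins, closure
#'   based), or `"enriched"` (terms over-represented among the proteins
#'   versus the annotated background; one-sided hypergeometric test,
#'   Benjamini-Hochberg FDR < `fdr`).
#' @param fdr FDR threshold for `"enriched"`.
#' @return character vector of terms, or a named numeric count vector
#'   for `"multiset"`.
#' @export
term_sets <- function(proteins, corpus,
                      mode = c("closure", "direct", "multiset", "enriched"),
                      fdr = 0.05) {
  mode <- match.arg(mode)
  ann <- corpus$annotations[intersect(proteins, names(corpus$annotations))]
  if (!length(ann)) {
    warning("no annotated proteins in query set")
    return(if (mode == "multiset") stats::setNames(numeric(0), character(0))
           else character(0))
  }
  closures <- lapply(ann, function(d) unique(unlist(corpus$ancestors[d])))
  switch(mode,
    direct = sort(unique(unlist(ann))),
    closure = sort(unique(unlist(closures))),
    multiset = {
      tab <- table(unlist(closures))
      stats::setNames(as.numeric(tab), names(tab))
    },
    enriched = {
      k <- length(closures)                      # annotated query proteins
      N <- corpus$n_proteins
      terms <- sort(unique(unlist(closures)))
      q <- table(factor(unlist(closures), levels = terms))
      m <- round(corpus$p[terms] * N)            # background proteins per term
      pval <- stats::phyper(as.numeric(q) - 1, m, N - m, k, lower.tail = FALSE)
      padj <- stats::p.adjust(pval, "BH")
      sort(terms[padj < fdr])
    })
}

#' Overlap score between two term collections
#'
#' Computes the Jaccard similarity or raw intersection size of two term
#' sets (character vectors) or multisets (named count vectors, where the
#' element-wise min/max formulas apply).
#'
#' @param U,V term collections from [term_sets()].
#' @param type `"jaccard"` or `"intersection"`.
#' @return a single numeric score; `NA` (with a warning) when both
#'   collections are empty.
#' @export
term_overlap <- function(U, V, type = c("jaccard", "intersection")) {
  type <- match.arg(type)
  if (!length(U) && !length(V)) {
    warning("both term collections empty; overlap undefined")
    return(NA_real_)
  }
  if (is.numeric(U) || is.numeric(V)) {
    terms <- union(names(U), names(V))
    u <- stats::setNames(numeric(length(terms)), terms); u[names(U)] <- U
    v <- stats::setNames(numeric(length(terms)), terms); v[names(V)] <- V
    inter <- sum(pmin(u, v)); uni <- sum(pmax(u, v))
  } else {
    inter <- length(intersect(U, V)); uni <- length(union(U, V))
  }
  if (type == "intersection") inter else inter / uni
}
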