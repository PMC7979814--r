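# Comparison baselines: target overlap, network proximity with
# degree-matched permutation nulls, and functional-overlap scores over
# the annotation corpus. Shortest-path statistics are computed on the
# protein-protein layer only.

#' Protein-protein layer as an igraph
#' @param graph an `msgraph`.
#' @return undirected igraph over all protein nodes.
#' @export
ppi_igraph <- function(graph) {
  e <- graph$edges[graph$edges$type == .pair_type("protein", "protein"), ,
                   drop = FALSE]
  prot <- graph$nodes$id[graph$nodes$kind == "protein"]
  igraph::graph_from_data_frame(e[c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = prot))
}

#' Drug-target and disease-protein sets
#' @param graph an `msgraph`.
#' @param id a drug or disease node id.
#' @return character vector of protein ids attached to `id`.
#' @export
protein_set <- function(graph, id) {
  e <- graph$edges
  hit <- e$from == id | e$to == id
  nb <- ifelse(e$from[hit] == id, e$to[hit], e$from[hit])
  nb[node_kind(graph, nb) == "protein"]
}

#' Jaccard overlap between drug targets and disease proteins
#' @param T drug-target protein set (character).
#' @param S disease-protein set (character).
#' @return `|T\U2229S| / |T\U222AS|` in [0, 1].
#' @export
protein_overlap <- function(T, S) {
  if (!length(T) || !length(S)) stop("protein sets must be nonempty")
  length(intersect(T, S)) / length(union(T, S))
}

#' Closest network distance from drug targets to disease proteins
#'
#' `d(S, T) = mean over t in T of min over s in S of l(s, t)` with `l`
#' the unweighted shortest-path length on the protein-protein layer.
#' Targets unreachable from every disease protein are dropped from the
#' mean with a warning.
#'
#' @param S disease-protein ids.
#' @param T drug-target ids.
#' @param ppi an igraph from [ppi_igraph()] (or an `msgraph`).
#' @return the mean closest distance.
#' @export
closest_distance <- function(S, T, ppi) {
  if (!length(T)) stop("drug-target set T must be nonempty")
  if (!length(S)) stop("disease-protein set S must be nonempty")
  if (inherits(ppi, "msgraph")) ppi <- ppi_igraph(ppi)
  D <- igraph::distances(ppi, v = T, to = S)
  mins <- apply(D, 1, min)
  if (any(!is.finite(mins))) {
    warning(sum(!is.finite(mins)), " unreachable target(s) dropped from mean")
    mins <- mins[is.finite(mins)]
  }
  if (!length(mins)) stop("no target reaches any disease protein")
  mean(mins)
}

# Degree bins: log2-spaced, merged upward until each holds at least
# `min_bin_size` nodes (the standard construction for proximity nulls).
.degree_bins <- function(ppi, min_bin_size) {
  deg <- igraph::degree(ppi)
  raw <- floor(log2(pmax(deg, 1)))
  lv <- sort(unique(raw))
  grp <- stats::setNames(integer(length(lv)), lv)
  g <- 1L; count <- 0L
  for (i in seq_along(lv)) {
    grp[i] <- g
    count <- count + sum(raw == lv[i])
    if (count >= min_bin_size && i < length(lv)) { g <- g + 1L; count <- 0L }
  }
  if (count < min_bin_size && g > 1L) grp[grp == g] <- g - 1L
  bin <- grp[as.character(raw)]
  if (min(table(bin)) < min_bin_size)
    stop("cannot build degree bins with >= ", min_bin_size,
         " members each; try a smaller min_bin_size")
  stats::setNames(bin, names(deg))
}

#' Degree-matched random node sets
#'
#' Draws `n_perm` random sets of the same cardinality as `nodes`, each
#' element sampled from the log2 degree bin of the node it replaces
#' (bins merged upward until every bin holds at least `min_bin_size`
#' nodes). Reproducible under `seed`.
#'
#' @param nodes character vector of protein ids.
#' @param ppi igraph from [ppi_igraph()] (or an `msgraph`).
#' @param n_perm number of sets.
#' @param seed RNG seed.
#' @param min_bin_size minimum bin occupancy (default 100; lower it for
#'   small fixtures).
#' @return list of character vectors.
#' @export
degree_matched_sample <- function(nodes, ppi, n_perm, seed = 1L,
                                  min_bin_size = 100L) {
  if (inherits(ppi, "msgraph")) ppi <- ppi_igraph(ppi)
  bins <- .degree_bins(ppi, min_bin_size)
  if (anyNA(bins[nodes])) stop("node(s) not in PPI layer")
  members <- split(names(bins), bins)
  .with_seed(seed, lapply(seq_len(n_perm), function(i) {
    out <- character(length(nodes))
    for (k in seq_along(nodes)) {
      pool <- setdiff(members[[as.character(bins[[nodes[k]]])]], out)
      out[k] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    out
  }))
}

.permutation_null <- function(observed, null, seed) {
  mu <- mean(null); sigma <- stats::sd(null)
  degenerate <- !is.finite(sigma) || sigma == 0
  structure(list(observed = observed, null = null, mu = mu, sigma = sigma,
                 z = if (degenerate) NA_real_ else (observed - mu) / sigma,
                 degenerate = degenerate, n_perm = length(null), seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null (", x$n_perm, " draws): observed = ",
      signif(x$observed, 4), ", mu = ", signif(x$mu, 4), ", sigma = ",
      signif(x$sigma, 4), ", z = ", signif(x$z, 4), "\n", sep = "")
  invisible(x)
}

#' Network proximity z-score between disease proteins and drug targets
#'
#' Compares the observed closest distance `d(S, T)` to a reference
#' distribution obtained by degree-matched resampling of both sets;
#' `z = (d - mu) / sigma`. More negative z means the drug targets sit
#' closer to the disease module than expected by chance, so `-z` is the
#' ranking score under the larger-is-better convention.
#'
#' @param S disease-protein ids.
#' @param T drug-target ids.
#' @param graph an `msgraph` (or a PPI igraph).
#' @param n_perm permutations (paper default 1000).
#' @param seed RNG seed.
#' @param min_bin_size degree-bin floor, see [degree_matched_sample()].
#' @return a `permutation_null`; `z` is `NA` and `degenerate` is `TRUE`
#'   when the null has zero spread.
#' @export
proximity_zscore <- function(S, T, graph, n_perm = 1000L, seed = 1L,
                             min_bin_size = 100L) {
  if (n_perm < 2L) stop("need n_perm >= 2 to estimate a null sd")
  ppi <- if (inherits(graph, "msgraph")) ppi_igraph(graph) else graph
  obs <- closest_distance(S, T, ppi)
  Ss <- degree_matched_sample(S, ppi, n_perm, seed, min_bin_size)
  Ts <- degree_matched_sample(T, ppi, n_perm, seed + 1L, min_bin_size)
  null <- vapply(seq_len(n_perm), function(i)
    suppressWarnings(closest_distance(Ss[[i]], Ts[[i]], ppi)), numeric(1))
  out <- .permutation_null(obs, null, seed)
  if (out$degenerate) warning("degenerate null (sigma = 0); z undefined")
  out
}

#' z-scored functional overlap between two protein sets
#'
#' Computes a term-overlap statistic for the observed protein sets and
#' z-scores it against degree-matched permutations of both sets (the
#' permuted sets are re-annotated through the corpus before scoring).
#'
#' @param S,T protein id sets (disease proteins, drug targets).
#' @param graph an `msgraph`.
#' @param corpus an `annotation_corpus` for the same graph.
#' @param mode term collection mode, `"closure"` or `"multiset"`.
#' @param type `"jaccard"` or `"intersection"`.
#' @param n_perm,seed,min_bin_size as in [proximity_zscore()].
#' @return a `permutation_null`.
#' @export
zscored_term_overlap <- function(S, T, graph, corpus,
                                 mode = c("closure", "multiset"),
                                 type = c("jaccard", "intersection"),
                                 n_perm = 1000L, seed = 1L,
                                 min_bin_size = 100L) {
  mode <- match.arg(mode); type <- match.arg(type)
  ppi <- ppi_igraph(graph)
  stat <- function(s, t) {
    suppressWarnings(term_overlap(term_sets(t, corpus, mode),
                                  term_sets(s, corpus, mode), type))
  }
  obs <- stat(S, T)
  Ss <- degree_matched_sample(S, ppi, n_perm, seed, min_bin_size)
  Ts <- degree_matched_sample(T, ppi, n_perm, seed + 1L, min_bin_size)
  null <- vapply(seq_len(n_perm), function(i) stat(Ss[[i]], Ts[[i]]), numeric(1))
  null[is.na(null)] <- 0
  .permutation_null(obs, null, seed)
}

#' Distance z-score for a protein pair sharing a biological function
#'
#' For two proteins with at least one common *direct* annotation,
#' compares their shortest-path distance on the PPI layer to distances
#' between degree-matched random pairs. Negative z: closer than chance.
#'
#' @param pair character(2) protein ids.
#' @param graph an `msgraph`.
#' @param corpus an `annotation_corpus` (used to check the shared direct
#'   annotation; skip the check with `require_shared = FALSE`).
#' @param n_perm,seed,min_bin_size as in [proximity_zscore()].
#' @param require_shared enforce the shared-direct-annotation
#'   precondition.
#' @return a `permutation_null`.
#' @export
shared_function_distance_zscore <- function(pair, graph, corpus = NULL,
                                            n_perm = 1000L, seed = 1L,
                                            min_bin_size = 100L,
                                            require_shared = TRUE) {
  if (n_perm < 2L) stop("need n_perm >= 2")
  stopifnot(length(pair) == 2L)
  if (require_shared) {
    if (is.null(corpus)) corpus <- annotation_corpus(graph)
    shared <- intersect(corpus$annotations[[pair[1]]],
                        corpus$annotations[[pair[2]]])
    if (!length(shared))
      stop("proteins ", pair[1], " and ", pair[2],
           " share no direct annotation")
  }
  ppi <- ppi_igraph(graph)
  d_obs <- igraph::distances(ppi, v = pair[1], to = pair[2])[1, 1]
  if (!is.finite(d_obs)) {
    warning("pair is disconnected on the PPI layer; excluded")
    return(NULL)
  }
  draws <- degree_matched_sample(pair, ppi, n_perm, seed, min_bin_size)
  null <- vapply(draws, function(pr) {
    d <- igraph::distances(ppi, v = pr[1], to = pr[2])[1, 1]
    if (is.finite(d)) d else NA_real_
  }, numeric(1))
  null <- null[is.finite(null)]
  if (length(null) < 2L) stop("null distribution empty after dropping disconnected pairs")
  .permutation_null(d_obs, null, seed)
}
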