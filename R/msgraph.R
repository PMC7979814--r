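#' @importFrom stats setNames
NULL

# Canonical node kinds. The kind set is open: extra kinds (e.g. anatomical
# entities) can be declared at assembly time together with the kind pairs
# they are allowed to form edges with.
.default_kinds <- c("drug", "disease", "protein", "biological_function")

.default_pairs <- function() {
  rbind(
    c("drug", "protein"),
    c("disease", "protein"),
    c("protein", "protein"),
    c("protein", "biological_function"),
    c("biological_function", "biological_function")
  )
}

.pair_type <- function(k1, k2) {
  a <- pmin(k1, k2)
  b <- pmax(k1, k2)
  paste(a, b, sep = "|")
}

#' Read a typed edge table
#'
#' Edge tables are UTF-8 TSV files with a header row and columns
#' `node_1`, `node_1_type`, `node_2`, `node_2_type`. For hierarchy tables
#' (function-function edges) orientation is implied by column order:
#' `node_1` is the child (more specific term) and `node_2` its parent.
#' Exact duplicate rows are collapsed with a message reporting the count.
#'
#' @param path path to a TSV file.
#' @param expected_kinds optional character(2); when given, the
#'   `node_*_type` columns are checked against it.
#' @return a data.frame with columns `node_1`, `node_1_type`, `node_2`,
#'   `node_2_type`.
#' @export
load_edge_table <- function(path, expected_kinds = NULL) {
  if (!file.exists(path)) stop("edge table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, quote = "")
  required <- c("node_1", "node_1_type", "node_2", "node_2_type")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("edge table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  tab <- tab[required]
  if (nrow(tab) == 0L) stop("edge table ", path, " contains no edges")
  dup <- duplicated(tab)
  if (any(dup)) {
    message(sum(dup), " duplicate row(s) collapsed in ", basename(path))
    tab <- tab[!dup, , drop = FALSE]
  }
  if (!is.null(expected_kinds)) {
    ok <- tab$node_1_type == expected_kinds[1] & tab$node_2_type == expected_kinds[2]
    if (!all(ok))
      stop("edge table ", path, " contains kinds other than (",
           expected_kinds[1], ", ", expected_kinds[2], ")")
  }
  rownames(tab) <- NULL
  tab
}

#' Assemble a multiscale interactome graph
#'
#' Builds a validated heterogeneous graph from the five edge layers:
#' drug-protein targets, disease-protein associations, protein-protein
#' physical interactions, protein-function annotations, and the directed
#' function hierarchy (child -> parent). Node identifiers must be unique
#' across kinds; an identifier appearing under two kinds is an error.
#' Duplicate edges (within or across tables) are merged with a message.
#'
#' @param drug_protein,disease_protein,ppi,protein_function,hierarchy
#'   edge tables as returned by [load_edge_table()]; `protein_function`
#'   and `hierarchy` may be `NULL` to build a molecular-scale graph.
#' @param extra_layers optional named list of additional edge tables; the
#'   name of each element is ignored, kinds are taken from the
#'   `node_*_type` columns and their pair is added to the permitted set.
#' @return an object of class `msgraph` with elements `nodes`
#'   (data.frame `id`, `kind`) and `edges` (data.frame `from`, `to`,
#'   `type`; hierarchy rows are oriented child -> parent).
#' @export
assemble_graph <- function(drug_protein, disease_protein, ppi,
                           protein_function = NULL, hierarchy = NULL,
                           extra_layers = NULL) {
  layers <- list(
    list(tab = drug_protein,     kinds = c("drug", "protein"),    directed = FALSE),
    list(tab = disease_protein,  kinds = c("disease", "protein"), directed = FALSE),
    list(tab = ppi,              kinds = c("protein", "protein"), directed = FALSE),
    list(tab = protein_function, kinds = c("protein", "biological_function"), directed = FALSE),
    list(tab = hierarchy,        kinds = c("biological_function", "biological_function"), directed = TRUE)
  )
  kinds <- .default_kinds
  pairs <- .default_pairs()
  for (xl in extra_layers) {
    k1 <- unique(xl$node_1_type); k2 <- unique(xl$node_2_type)
    if (length(k1) != 1L || length(k2) != 1L)
      stop("extra layers must have a single kind per endpoint column")
    kinds <- union(kinds, c(k1, k2))
    pairs <- rbind(pairs, c(k1, k2))
    layers[[length(layers) + 1L]] <- list(tab = xl, kinds = c(k1, k2),
                                          directed = FALSE)
  }

  node_kind <- list()
  edge_rows <- list()
  for (ly in layers) {
    if (is.null(ly$tab)) next
    tab <- ly$tab
    bad <- !(tab$node_1_type %in% kinds) | !(tab$node_2_type %in% kinds)
    if (any(bad))
      stop("unknown node kind(s): ",
           paste(unique(c(tab$node_1_type[bad], tab$node_2_type[bad])), collapse = ", "))
    exp_t <- .pair_type(ly$kinds[1], ly$kinds[2])
    got_t <- .pair_type(tab$node_1_type, tab$node_2_type)
    if (any(got_t != exp_t))
      stop("edge between kinds (", tab$node_1_type[got_t != exp_t][1], ", ",
           tab$node_2_type[got_t != exp_t][1], ") not permitted in a (",
           ly$kinds[1], ", ", ly$kinds[2], ") table")
    node_kind[[length(node_kind) + 1L]] <-
      data.frame(id = c(tab$node_1, tab$node_2),
                 kind = c(tab$node_1_type, tab$node_2_type))
    if (ly$directed) {
      from <- tab$node_1; to <- tab$node_2           # child -> parent
    } else {
      from <- pmin(tab$node_1, tab$node_2)
      to   <- pmax(tab$node_1, tab$node_2)
      swap <- tab$node_1 != from                      # keep kinds aligned
      k1 <- ifelse(swap, tab$node_2_type, tab$node_1_type)
      k2 <- ifelse(swap, tab$node_1_type, tab$node_2_type)
      tab$node_1_type <- k1; tab$node_2_type <- k2
    }
    edge_rows[[length(edge_rows) + 1L]] <-
      data.frame(from = from, to = to,
                 type = .pair_type(tab$node_1_type, tab$node_2_type))
  }
  nodes <- unique(do.call(rbind, node_kind))
  clash <- nodes$id[duplicated(nodes$id)]
  if (length(clash))
    stop("identifier(s) appear under more than one kind: ",
         paste(unique(clash), collapse = ", "))
  edges <- do.call(rbind, edge_rows)
  loop <- edges$from == edges$to
  if (any(loop)) {
    message(sum(loop), " self-loop(s) dropped")
    edges <- edges[!loop, , drop = FALSE]
  }
  dup <- duplicated(edges[c("from", "to", "type")])
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) merged across tables")
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges),
                 kinds = kinds, pairs = pairs,
                 token = paste(sample(c(letters, 0:9), 12, TRUE), collapse = ""),
                 class = "msgraph")
  validate_msgraph(g)
  g
}

#' Validate a multiscale graph
#'
#' Checks the structural invariants: unique node ids, no self-loops or
#' duplicate edges, and every edge between a permitted kind pair.
#' @param graph an `msgraph`.
#' @return the graph, invisibly.
#' @export
validate_msgraph <- function(graph) {
  stopifnot(inherits(graph, "msgraph"))
  if (anyDuplicated(graph$nodes$id)) stop("duplicate node identifiers")
  e <- graph$edges
  if (any(e$from == e$to)) stop("self-loop present")
  if (anyDuplicated(e[c("from", "to")])) stop("duplicate edge present")
  kind <- node_kind(graph, c(e$from, e$to))
  if (anyNA(kind)) stop("edge endpoint not in node table")
  n <- nrow(e)
  tpair <- .pair_type(kind[seq_len(n)], kind[n + seq_len(n)])
  allowed <- .pair_type(attr(graph, "pairs")[, 1], attr(graph, "pairs")[, 2])
  bad <- !(tpair %in% allowed)
  if (any(bad))
    stop("edge(s) between non-permitted kind pair: ",
         paste(unique(tpair[bad]), collapse = ", "))
  if (any(tpair != e$type)) stop("edge type column inconsistent with node kinds")
  invisible(graph)
}

#' Look up node kinds
#' @param graph an `msgraph`.
#' @param ids node identifiers.
#' @return character vector of kinds (NA for unknown ids).
#' @export
node_kind <- function(graph, ids) {
  graph$nodes$kind[match(ids, graph$nodes$id)]
}

#' @export
print.msgraph <- function(x, ...) {
  cat("Multiscale interactome graph\n")
  cat("  nodes:", nrow(x$nodes), "\n")
  for (k in sort(unique(x$nodes$kind)))
    cat(sprintf("    %-22s %d\n", k, sum(x$nodes$kind == k)))
  cat("  edges:", nrow(x$edges), "\n")
  for (t in sort(unique(x$edges$type)))
    cat(sprintf("    %-42s %d\n", t, sum(x$edges$type == t)))
  invisible(x)
}

.hierarchy_edges <- function(graph) {
  graph$edges[graph$edges$type == .pair_type("biological_function",
                                             "biological_function"), , drop = FALSE]
}

.annotation_edges <- function(graph) {
  graph$edges[graph$edges$type == .pair_type("protein", "biological_function"), ,
              drop = FALSE]
}

# igraph view of the function hierarchy, edges child -> parent
.hierarchy_igraph <- function(graph) {
  h <- .hierarchy_edges(graph)
  fn <- graph$nodes$id[graph$nodes$kind == "biological_function"]
  igraph::graph_from_data_frame(h[c("from", "to")], directed = TRUE,
                                vertices = data.frame(name = fn))
}

#' Prune biological functions not reachable from any annotated protein
#'
#' Keeps exactly the function nodes that are annotated -- directly, or
#' implicitly through any descendant in the hierarchy -- to at least one
#' drug target or disease protein. All other function nodes and their
#' incident edges are removed. The hierarchy must be acyclic.
#'
#' @param graph an `msgraph`.
#' @return the pruned `msgraph`.
#' @export
prune_functions <- function(graph) {
  drug_t <- .pair_type("drug", "protein")
  dis_t  <- .pair_type("disease", "protein")
  de <- graph$edges[graph$edges$type %in% c(drug_t, dis_t), , drop = FALSE]
  anchor_prot <- unique(c(de$from, de$to))
  anchor_prot <- anchor_prot[node_kind(graph, anchor_prot) == "protein"]
  if (!length(anchor_prot)) stop("no drug targets or disease proteins in graph")

  ann <- .annotation_edges(graph)
  ann_fun <- ifelse(node_kind(graph, ann$from) == "biological_function",
                    ann$from, ann$to)
  ann_pro <- ifelse(node_kind(graph, ann$from) == "protein", ann$from, ann$to)
  seed <- unique(ann_fun[ann_pro %in% anchor_prot])

  hg <- .hierarchy_igraph(graph)
  if (!igraph::is_dag(hg)) stop("function hierarchy contains a cycle")
  keep <- character(0)
  if (length(seed)) {
    # ancestors = terms reachable along child -> parent edges, plus the seeds
    keep <- unique(unlist(lapply(seed, function(s)
      names(igraph::subcomponent(hg, s, mode = "out")))))
  }
  drop_fun <- setdiff(graph$nodes$id[graph$nodes$kind == "biological_function"],
                      keep)
  if (!length(drop_fun)) return(graph)
  graph$nodes <- graph$nodes[!(graph$nodes$id %in% drop_fun), , drop = FALSE]
  graph$edges <- graph$edges[!(graph$edges$from %in% drop_fun) &
                             !(graph$edges$to %in% drop_fun), , drop = FALSE]
  rownames(graph$nodes) <- rownames(graph$edges) <- NULL
  attr(graph, "token") <- paste(sample(c(letters, 0:9), 12, TRUE), collapse = "")
  validate_msgraph(graph)
  graph
}

#' Remove biological function nodes (molecular-scale view)
#'
#' Drops all function nodes and their incident edges, leaving the
#' molecular-scale interactome of drugs, diseases and proteins.
#' @param graph an `msgraph`.
#' @return the reduced `msgraph`.
#' @export
remove_function_nodes <- function(graph) {
  fn <- graph$nodes$id[graph$nodes$kind == "biological_function"]
  graph$nodes <- graph$nodes[!(graph$nodes$id %in% fn), , drop = FALSE]
  graph$edges <- graph$edges[!(graph$edges$from %in% fn) &
                             !(graph$edges$to %in% fn), , drop = FALSE]
  rownames(graph$nodes) <- rownames(graph$edges) <- NULL
  attr(graph, "token") <- paste(sample(c(letters, 0:9), 12, TRUE), collapse = "")
  graph
}

#' Write a graph back to the five edge tables
#'
#' Emits one TSV per layer (drug_protein.tsv, disease_protein.tsv,
#' ppi.tsv, protein_function.tsv, hierarchy.tsv) in the loader schema so
#' that reloading reproduces the graph exactly.
#' @param graph an `msgraph`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_edge_tables <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- list(drug_protein = c("drug", "protein"),
                 disease_protein = c("disease", "protein"),
                 ppi = c("protein", "protein"),
                 protein_function = c("protein", "biological_function"),
                 hierarchy = c("biological_function", "biological_function"))
  out <- character(0)
  kind <- function(ids) node_kind(graph, ids)
  for (nm in names(layers)) {
    ks <- layers[[nm]]
    e <- graph$edges[graph$edges$type == .pair_type(ks[1], ks[2]), , drop = FALSE]
    if (!nrow(e)) next
    # orient rows so node_1 carries the layer's first kind (hierarchy rows
    # are already stored child -> parent and both endpoints are functions)
    swap <- nm != "hierarchy" & kind(e$from) != ks[1]
    n1 <- ifelse(swap, e$to, e$from); n2 <- ifelse(swap, e$from, e$to)
    tab <- data.frame(node_1 = n1, node_1_type = kind(n1),
                      node_2 = n2, node_2_type = kind(n2))
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, p)
  }
  invisible(out)
}

#' Load a graph from a fixture directory written by [write_edge_tables()]
#' @param dir directory containing the edge-table TSVs.
#' @return an `msgraph`.
#' @export
read_edge_tables <- function(dir) {
  rd <- function(nm, kinds) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(p)) load_edge_table(p, kinds) else NULL
  }
  assemble_graph(
    drug_protein = rd("drug_protein", c("drug", "protein")),
    disease_protein = rd("disease_protein", c("disease", "protein")),
    ppi = rd("ppi", c("protein", "protein")),
    protein_function = rd("protein_function", c("protein", "biological_function")),
    hierarchy = rd("hierarchy", c("biological_function", "biological_function"))
  )
}

#' Construct a treatment dataset of approved drug-disease pairs
#'
#' @param pairs data.frame with columns `drug`, `disease` (or a path to a
#'   TSV with that header).
#' @param graph the `msgraph` the identifiers refer to.
#' @return data.frame of unique pairs, class `treatment_dataset`.
#' @export
treatment_dataset <- function(pairs, graph) {
  if (is.character(pairs) && length(pairs) == 1L)
    pairs <- utils::read.delim(pairs, colClasses = "character")
  if (!all(c("drug", "disease") %in% names(pairs)))
    stop("treatment pairs need columns 'drug' and 'disease'")
  pairs <- unique(pairs[c("drug", "disease")])
  kd <- node_kind(graph, pairs$drug); kx <- node_kind(graph, pairs$disease)
  if (any(is.na(kd) | kd != "drug"))
    stop("unknown drug id(s): ", paste(pairs$drug[is.na(kd) | kd != "drug"], collapse = ", "))
  if (any(is.na(kx) | kx != "disease"))
    stop("unknown disease id(s): ", paste(pairs$disease[is.na(kx) | kx != "disease"], collapse = ", "))
  deg_ids <- c(graph$edges$from, graph$edges$to)
  if (!all(pairs$drug %in% deg_ids) || !all(pairs$disease %in% deg_ids))
    stop("every drug and disease in the dataset must have at least one edge")
  rownames(pairs) <- NULL
  class(pairs) <- c("treatment_dataset", "data.frame")
  pairs
}

#' Construct pharmacogenomic (drug, disease, gene) triplets
#'
#' Each triplet records a gene whose variation is known to alter the
#' given treatment. The (drug, disease) pair must be an approved pair of
#' the dataset and the gene must resolve to a protein node.
#' @param triplets data.frame with columns `drug`, `disease`, `gene`
#'   (or a TSV path).
#' @param dataset a `treatment_dataset`.
#' @param graph the `msgraph`.
#' @return data.frame of triplets, class `pgx_triplets`.
#' @export
pgx_triplets <- function(triplets, dataset, graph) {
  if (is.character(triplets) && length(triplets) == 1L)
    triplets <- utils::read.delim(triplets, colClasses = "character")
  if (!all(c("drug", "disease", "gene") %in% names(triplets)))
    stop("pgx triplets need columns 'drug', 'disease', 'gene'")
  triplets <- unique(triplets[c("drug", "disease", "gene")])
  key <- paste(triplets$drug, triplets$disease)
  ok <- key %in% paste(dataset$drug, dataset$disease)
  if (!all(ok))
    stop("triplet (drug, disease) not an approved pair: ",
         paste(unique(key[!ok]), collapse = "; "))
  kg <- node_kind(graph, triplets$gene)
  if (any(is.na(kg) | kg != "protein"))
    stop("gene id(s) do not resolve to protein nodes: ",
         paste(triplets$gene[is.na(kg) | kg != "protein"], collapse = ", "))
  rownames(triplets) <- NULL
  class(triplets) <- c("pgx_triplets", "data.frame")
  triplets
}
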