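#' Edge-type weight configuration for biased walks
#'
#' The random walker splits its continuation probability across the node
#' *types* adjacent to its current node in proportion to these weights,
#' then uniformly across the neighbors of the chosen type. Function
#' neighbors of a function node are weighted separately depending on
#' whether they sit higher (parent) or lower (child) in the hierarchy.
#' Defaults are the optimized multiscale weights
#' (w_drug = 3.21, w_disease = 3.54, w_protein = 4.40,
#' w_biological_function = 6.58, w_higher = 2.10, w_lower = 4.49,
#' alpha = 0.860).
#'
#' @param w_drug,w_disease,w_protein,w_biological_function,w_higher_level_function,w_lower_level_function
#'   positive type weights.
#' @param alpha probability of continuing the walk (restart probability is
#'   `1 - alpha`); must lie in (0, 1).
#' @param eps L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap guarding non-convergence.
#' @param extra optional named list of weights for additional node kinds.
#' @param enforce_sum when `TRUE`, require
#'   `w_biological_function == w_higher_level_function + w_lower_level_function`
#'   (the sweep convention).
#' @return an object of class `edge_weights`.
#' @export
edge_weights <- function(w_drug = 3.21, w_disease = 3.54, w_protein = 4.40,
                         w_biological_function = 6.58,
                         w_higher_level_function = 2.10,
                         w_lower_level_function = 4.49,
                         alpha = 0.860, eps = 1e-6, max_iter = 10000L,
                         extra = NULL, enforce_sum = FALSE) {
  w <- c(drug = w_drug, disease = w_disease, protein = w_protein,
         biological_function = w_biological_function,
         higher_level_function = w_higher_level_function,
         lower_level_function = w_lower_level_function,
         unlist(extra))
  if (any(w <= 0)) stop("all type weights must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (eps <= 0) stop("eps must be positive")
  if (enforce_sum &&
      abs(w_biological_function -
          (w_higher_level_function + w_lower_level_function)) > 1e-9)
    stop("w_biological_function must equal w_higher + w_lower under enforce_sum")
  structure(list(weights = w, alpha = alpha, eps = eps,
                 max_iter = as.integer(max_iter)),
            class = "edge_weights")
}

#' @export
print.edge_weights <- function(x, ...) {
  cat("Edge-type weights (alpha =", x$alpha, ", eps =", x$eps, ")\n")
  print(x$weights)
  invisible(x)
}

#' Directed per-focal-node view of the graph
#'
#' Replaces every undirected edge by a pair of directed edges, then makes
#' the focal drug or disease a source (no in-edges) and all other drugs
#' and diseases sinks (no out-edges). Walks therefore never use drugs or
#' diseases as intermediates. Nodes whose out-degree drops to zero by the
#' construction (e.g. a protein whose only neighbor is the focal drug)
#' join the sink set as well.
#'
#' @param graph an `msgraph`.
#' @param focal a drug or disease node id.
#' @return a list of class `directed_view` with integer-indexed directed
#'   edges, their relative neighbor types, and the sink index set.
#' @export
directed_view <- function(graph, focal) {
  ids <- graph$nodes$id
  kinds <- graph$nodes$kind
  fi <- match(focal, ids)
  if (is.na(fi)) stop("focal node not in graph: ", focal)
  if (!(kinds[fi] %in% c("drug", "disease")))
    stop("focal node must be a drug or disease, got kind ", kinds[fi])

  e <- graph$edges
  a <- match(e$from, ids); b <- match(e$to, ids)
  hier <- e$type == .pair_type("biological_function", "biological_function")
  # direction a -> b: neighbor type is kind(b); for hierarchy edges the
  # stored orientation is child -> parent, so b is the higher-level term.
  rel_ab <- ifelse(hier, "higher_level_function", kinds[b])
  rel_ba <- ifelse(hier, "lower_level_function", kinds[a])
  di <- c(a, b); dj <- c(b, a); rel <- c(rel_ab, rel_ba)

  keep <- dj != fi                                   # focal has no in-edges
  sinky <- kinds[di] %in% c("drug", "disease") & di != fi
  keep <- keep & !sinky                              # other drugs/diseases: no out
  di <- di[keep]; dj <- dj[keep]; rel <- rel[keep]

  outdeg <- tabulate(di, nbins = length(ids))
  sinks <- which(outdeg == 0L)
  if (outdeg[fi] == 0L)
    warning("focal node '", focal, "' has no out-edges; its profile is the restart vector")
  structure(list(ids = ids, kinds = kinds, focal = focal, focal_idx = fi,
                 i = di, j = dj, rel = rel, sinks = sinks,
                 token = attr(graph, "token")),
            class = "directed_view")
}

.rel_weight <- function(rel, config) {
  w <- config$weights[rel]
  if (anyNA(w))
    stop("no weight configured for neighbor kind(s): ",
         paste(unique(rel[is.na(w)]), collapse = ", "))
  unname(w)
}

#' Biased transition matrix of a directed view
#'
#' For a walker at node i with adjacent type set T, the probability of
#' stepping to a specific neighbor j of type t is
#' `(w_t / sum(w_t', t' in T)) / n_t`, where `n_t` is the number of
#' type-t out-neighbors. Rows of sink nodes are all zero; every other
#' row sums to one.
#'
#' @param view a `directed_view`.
#' @param config an `edge_weights` configuration.
#' @return a sparse `dgCMatrix` transition matrix.
#' @export
transition_matrix <- function(view, config) {
  n <- length(view$ids)
  if (!length(view$i))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  w <- .rel_weight(view$rel, config)
  key <- paste(view$i, view$rel)
  first <- !duplicated(key)
  denom_tab <- rowsum(w[first], view$i[first])
  denom <- denom_tab[match(as.character(view$i), rownames(denom_tab)), 1L]
  n_t <- stats::ave(rep(1, length(key)), key, FUN = sum)
  p <- (w / denom) / n_t
  M <- Matrix::sparseMatrix(i = view$i, j = view$j, x = p, dims = c(n, n))
  rs <- Matrix::rowSums(M)
  nonsink <- setdiff(seq_len(n), view$sinks)
  stopifnot(all(abs(rs[nonsink] - 1) < 1e-12), all(rs[view$sinks] == 0))
  M
}

.new_profile <- function(r, view, config, iterations, residual, method) {
  names(r) <- view$ids
  structure(r, focal = view$focal, alpha = config$alpha,
            iterations = iterations, residual = residual, method = method,
            class = "diffusion_profile")
}

#' Power iteration for diffusion profiles
#'
#' Iterates
#' `r(k+1) = (1 - alpha) s + alpha (r(k) M + s * sum(r(k)[sinks]))`
#' from the uniform vector until the L1 change drops below `eps`. Mass
#' reaching a sink node is returned to the restart vector on the next
#' step, so every iterate sums to one.
#'
#' @param M transition matrix from [transition_matrix()].
#' @param s restart vector (non-negative, sums to one).
#' @param config an `edge_weights` (supplies `alpha`, `eps`, `max_iter`).
#' @param sinks integer indices of sink rows.
#' @return list with elements `r`, `iterations`, `residual`.
#' @export
power_iteration <- function(M, s, config, sinks) {
  stopifnot(all(s >= 0), abs(sum(s) - 1) < 1e-9)
  n <- length(s)
  alpha <- config$alpha
  r <- rep(1 / n, n)
  Mt <- Matrix::t(M)                      # column access -> fast crossprod
  for (k in seq_len(config$max_iter)) {
    rn <- (1 - alpha) * s +
      alpha * (as.vector(Mt %*% r) + s * sum(r[sinks]))
    res <- sum(abs(rn - r))
    if (abs(sum(rn) - 1) > 1e-9)
      stop("mass conservation violated at iteration ", k)
    r <- rn
    if (res <= config$eps)
      return(list(r = r, iterations = k, residual = res))
  }
  stop("power iteration did not converge within ", config$max_iter,
       " iterations (residual ", signif(res, 3), ")")
}

#' Exact linear-solve oracle for diffusion profiles
#'
#' Solves the fixed point of the power iteration directly: sink rows of M
#' are replaced by the restart vector (sink mass restarts), and
#' `r = (1 - alpha) s (I - alpha M')^{-1}` is obtained by a dense solve.
#' Intended as an independent reference for testing; guarded to small
#' graphs.
#'
#' @param view a `directed_view`.
#' @param config an `edge_weights`.
#' @param s optional restart vector; defaults to the focal indicator.
#' @return a `diffusion_profile`.
#' @export
exact_profile_oracle <- function(view, config, s = NULL) {
  n <- length(view$ids)
  if (n > 2000) stop("dense oracle guarded to graphs with <= 2000 nodes")
  if (is.null(s)) { s <- numeric(n); s[view$focal_idx] <- 1 }
  M <- as.matrix(transition_matrix(view, config))
  if (length(view$sinks))
    M[view$sinks, ] <- matrix(s, nrow = length(view$sinks), ncol = n, byrow = TRUE)
  A <- diag(n) - config$alpha * M
  r <- drop(solve(t(A), (1 - config$alpha) * s))
  stopifnot(abs(sum(r) - 1) < 1e-8)
  .new_profile(r, view, config, iterations = NA_integer_, residual = 0,
               method = "exact")
}

# nodes reachable from the focal along directed-view edges
.reachable <- function(view) {
  n <- length(view$ids)
  g <- igraph::make_graph(rbind(view$i, view$j), n = n, directed = TRUE)
  out <- logical(n)
  out[as.integer(igraph::subcomponent(g, view$focal_idx, mode = "out"))] <- TRUE
  out
}

.profile_cache <- new.env(parent = emptyenv())

.cache_key <- function(token, focal, config) {
  paste(token, focal, paste(signif(config$weights, 12), collapse = ","),
        config$alpha, sep = "|")
}

#' Diffusion profile of a drug or disease
#'
#' Composes the directed view, the biased transition matrix and the power
#' iteration into the visitation-frequency vector of the focal node's
#' restart-biased random walk. Results are memoized per (graph, weights,
#' focal) within a session; set `options(msinteractome.cache = FALSE)` to
#' disable.
#'
#' @param graph an `msgraph`.
#' @param config an `edge_weights`.
#' @param focal a drug or disease node id.
#' @param method `"power"` (default) or `"exact"` (dense oracle).
#' @return a named `diffusion_profile` vector over all graph nodes.
#' @export
diffusion_profile <- function(graph, config, focal, method = c("power", "exact")) {
  method <- match.arg(method)
  use_cache <- isTRUE(getOption("msinteractome.cache", TRUE)) &&
    method == "power"
  key <- .cache_key(attr(graph, "token"), focal, config)
  if (use_cache && !is.null(.profile_cache[[key]]))
    return(.profile_cache[[key]])
  view <- directed_view(graph, focal)
  if (method == "exact") {
    prof <- exact_profile_oracle(view, config)
  } else {
    M <- transition_matrix(view, config)
    s <- numeric(length(view$ids)); s[view$focal_idx] <- 1
    fit <- power_iteration(M, s, config, view$sinks)
    r <- fit$r
    # the fixed point is exactly zero off the reachable set; the uniform
    # initialization leaves geometrically decaying residue there, which we
    # remove before reporting
    reach <- .reachable(view)
    if (!all(reach)) { r[!reach] <- 0; r <- r / sum(r) }
    prof <- .new_profile(r, view, config, fit$iterations, fit$residual,
                         "power")
  }
  if (use_cache) .profile_cache[[key]] <- prof
  prof
}

#' Diffusion profiles for many focal nodes
#'
#' @param graph an `msgraph`.
#' @param config an `edge_weights`.
#' @param focals character vector of drug/disease ids.
#' @return numeric matrix, nodes x focal entities.
#' @export
compute_profiles <- function(graph, config, focals) {
  out <- vapply(focals, function(f)
    as.numeric(diffusion_profile(graph, config, f)),
    numeric(nrow(graph$nodes)))
  rownames(out) <- graph$nodes$id
  out
}

#' Write diffusion profiles as TSV
#' @param profiles matrix from [compute_profiles()].
#' @param path output file; one row per (focal, node) with the visitation
#'   frequency.
#' @return invisibly, `path`.
#' @export
write_profiles_tsv <- function(profiles, path) {
  long <- data.frame(
    focal = rep(colnames(profiles), each = nrow(profiles)),
    node_id = rep(rownames(profiles), times = ncol(profiles)),
    visitation_frequency = as.vector(profiles))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
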