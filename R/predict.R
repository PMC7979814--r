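#' Similarity metrics over diffusion profiles
#'
#' The seven comparison metrics between a drug profile `rc` and a disease
#' profile `rd`. Distances (L2, L1, Canberra, correlation distance) are
#' negated so that a larger score always means a more likely treatment;
#' cosine similarity and the two proximity readouts are returned as-is.
#' Canberra terms with a 0/0 denominator are defined as 0. A profile with
#' zero variance under the correlation metric is treated as maximally
#' distant (distance 2, score -2).
#'
#' @param rc drug diffusion profile (named numeric).
#' @param rd disease diffusion profile over the same node index.
#' @param metric one of `"l2"`, `"l1"`, `"canberra"`, `"cosine"`,
#'   `"correlation"`, `"proximity_drug_in_disease"`, `"proximity_product"`.
#' @param drug,disease node ids, required by the proximity metrics.
#' @return a single numeric score (larger = more treatment-like).
#' @export
profile_similarity <- function(rc, rd,
                               metric = c("correlation", "l2", "l1", "canberra",
                                          "cosine", "proximity_drug_in_disease",
                                          "proximity_product"),
                               drug = NULL, disease = NULL) {
  metric <- match.arg(metric)
  if (length(rc) != length(rd) ||
      (!is.null(names(rc)) && !is.null(names(rd)) &&
       !identical(names(rc), names(rd))))
    stop("profiles are not over the same node index")
  x <- as.numeric(rc); y <- as.numeric(rd)
  switch(metric,
    l2 = -sqrt(sum((x - y)^2)),
    l1 = -sum(abs(x - y)),
    canberra = {
      num <- abs(x - y); den <- abs(x) + abs(y)
      t <- ifelse(den == 0, 0, num / den)
      -sum(t)
    },
    cosine = sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2))),
    correlation = {
      xc <- x - mean(x); yc <- y - mean(y)
      nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
      if (nx == 0 || ny == 0) {
        message("zero-variance profile under correlation metric; maximal distance assigned")
        -2
      } else -(1 - sum(xc * yc) / (nx * ny))
    },
    proximity_drug_in_disease = {
      if (is.null(drug)) stop("proximity metrics need the drug node id")
      unname(rd[drug])
    },
    proximity_product = {
      if (is.null(drug) || is.null(disease))
        stop("proximity_product needs drug and disease node ids")
      unname(rd[drug] * rc[disease])
    })
}

#' Rank candidate drugs for a disease
#'
#' Scores every candidate drug against the disease by comparing their
#' diffusion profiles and sorts by descending score; score ties are
#' broken by lexicographic drug id so rankings are deterministic.
#'
#' @param disease disease node id.
#' @param candidates character vector of drug ids.
#' @param profiles nodes x entities matrix from [compute_profiles()]
#'   containing columns for the disease and all candidates.
#' @param metric similarity metric, see [profile_similarity()].
#' @return data.frame (`drug`, `score`, `rank`) in rank order.
#' @export
rank_drugs <- function(disease, candidates, profiles, metric = "correlation") {
  missing <- setdiff(c(disease, candidates), colnames(profiles))
  if (length(missing))
    stop("no profile available for: ", paste(missing, collapse = ", "))
  rd <- profiles[, disease]
  score <- vapply(candidates, function(d)
    profile_similarity(profiles[, d], rd, metric, drug = d, disease = disease),
    numeric(1))
  o <- order(-score, candidates)
  data.frame(drug = candidates[o], score = score[o],
             rank = seq_along(candidates), row.names = NULL)
}

#' Evaluate per-disease drug rankings
#'
#' Computes per-disease AUROC (rank-based, ties averaged), average
#' precision and Recall@k, plus the aggregates used for model comparison:
#' the median AUROC, mean average precision and mean Recall@k across
#' diseases. Diseases without at least one positive and one negative
#' among their candidates are excluded with a warning.
#'
#' @param rankings named list (by disease id) of data.frames with columns
#'   `drug` and `score`, as returned by [rank_drugs()].
#' @param positives a `treatment_dataset` of approved pairs.
#' @param recall_k cutoff for Recall@k (default 50).
#' @return list of class `eval_report` with `per_disease` (data.frame)
#'   and `aggregate` (named numeric).
#' @export
evaluate_rankings <- function(rankings, positives, recall_k = 50L) {
  key <- paste(positives$drug, positives$disease)
  rows <- lapply(names(rankings), function(dz) {
    rk <- rankings[[dz]]
    lab <- paste(rk$drug, dz) %in% key
    if (!any(lab)) {
      warning("disease ", dz, " has no positive candidate; excluded")
      return(NULL)
    }
    if (all(lab)) {
      warning("disease ", dz, " has no negative candidate; excluded")
      return(NULL)
    }
    data.frame(disease = dz,
               n_candidates = nrow(rk), n_positives = sum(lab),
               auroc = auroc(rk$score, lab),
               average_precision = average_precision(rk$score, lab, rk$drug),
               recall_at_k = recall_at_k(rk$score, lab, recall_k, rk$drug))
  })
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no evaluable disease")
  agg <- c(median_auroc = stats::median(per$auroc),
           mean_average_precision = mean(per$average_precision),
           mean_recall_at_k = mean(per$recall_at_k))
  structure(list(per_disease = per, aggregate = agg, recall_k = recall_k),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Ranking evaluation over", nrow(x$per_disease), "diseases\n")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Five-fold cross-validated treatment ranking
#'
#' Drugs are shuffled by `seed` and partitioned into `n_folds` folds.
#' For each fold, every disease of the dataset ranks the held-out fold's
#' drugs; approved pairs are the positives and all other fold drugs are
#' negatives. Training-set reports rank the remaining drugs analogously.
#' The summary averages the held-out aggregates across folds.
#'
#' @param graph an `msgraph`.
#' @param dataset a `treatment_dataset`.
#' @param config an `edge_weights`.
#' @param metric similarity metric name.
#' @param seed integer fold-shuffling seed.
#' @param n_folds number of folds (default 5).
#' @param profiles optional precomputed profile matrix covering all drugs
#'   and diseases (avoids recomputation during sweeps).
#' @param recall_k Recall@k cutoff.
#' @return list of class `cv_result` with per-fold `eval_report`s
#'   (held-out and training) and the cross-fold `summary`.
#' @export
five_fold_cv <- function(graph, dataset, config, metric = "correlation",
                         seed = 1L, n_folds = 5L, profiles = NULL,
                         recall_k = 50L) {
  drugs <- sort(graph$nodes$id[graph$nodes$kind == "drug"])
  diseases <- sort(unique(dataset$disease))
  if (length(drugs) < n_folds) stop("need at least ", n_folds, " drugs")
  if (is.null(profiles))
    profiles <- compute_profiles(graph, config, c(drugs, diseases))
  fold_of <- .with_seed(seed, {
    sh <- sample(drugs)
    stats::setNames(rep_len(seq_len(n_folds), length(sh)), sh)[drugs]
  })
  eval_side <- function(cands) {
    rks <- lapply(diseases, function(dz) rank_drugs(dz, cands, profiles, metric))
    names(rks) <- diseases
    suppressWarnings(evaluate_rankings(rks, dataset, recall_k))
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    held <- drugs[fold_of == f]
    train <- drugs[fold_of != f]
    list(fold = f, held = eval_side(held), train = eval_side(train))
  })
  held_agg <- t(vapply(folds, function(f) f$held$aggregate, numeric(3)))
  train_agg <- t(vapply(folds, function(f) f$train$aggregate, numeric(3)))
  structure(list(folds = folds,
                 summary = colMeans(held_agg),
                 training_summary = colMeans(train_agg),
                 metric = metric, seed = seed, fold_of = fold_of),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated treatment ranking (", length(x$folds), " folds, metric = ",
      x$metric, ")\n", sep = "")
  cat("held-out (averaged across folds):\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Hyperparameter grid for the weight sweep
#'
#' Evenly spaced points per weight axis crossed into a grid, with
#' `w_biological_function = w_higher + w_lower` by convention. The
#' default resolution (3 points per weight axis, 2 alphas) yields 486
#' combinations over the standard ranges; a different `budget` truncates
#' or samples the cross-product under `seed`.
#'
#' @param budget number of configurations to keep (default 486).
#' @param seed sampling seed used when the full grid exceeds `budget`.
#' @param ranges named list of c(min, max) per axis (`w_drug`,
#'   `w_disease`, `w_protein`, `w_higher`, `w_lower`, `alpha`).
#' @param n_points points per weight axis (alpha gets `n_alpha`).
#' @param n_alpha points on the alpha axis.
#' @return data.frame, one row per configuration.
#' @export
make_weight_grid <- function(budget = 486L, seed = 1L,
                             ranges = list(w_drug = c(3, 9), w_disease = c(3, 9),
                                           w_protein = c(3, 9),
                                           w_higher = c(1.5, 4.5),
                                           w_lower = c(1.5, 4.5),
                                           alpha = c(0.85, 0.9)),
                             n_points = 3L, n_alpha = 2L) {
  if (budget < 1L) stop("empty weight grid requested")
  ax <- lapply(names(ranges), function(nm) {
    k <- if (nm == "alpha") n_alpha else n_points
    seq(ranges[[nm]][1], ranges[[nm]][2], length.out = k)
  })
  names(ax) <- names(ranges)
  grid <- expand.grid(ax, KEEP.OUT.ATTRS = FALSE)
  grid$w_biological_function <- grid$w_higher + grid$w_lower
  if (nrow(grid) == 0L) stop("empty weight grid")
  if (nrow(grid) > budget)
    grid <- grid[.with_seed(seed, sort(sample(nrow(grid), budget))), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

.grid_row_config <- function(row, base = edge_weights()) {
  edge_weights(w_drug = row$w_drug, w_disease = row$w_disease,
               w_protein = row$w_protein,
               w_biological_function = row$w_biological_function,
               w_higher_level_function = row$w_higher,
               w_lower_level_function = row$w_lower,
               alpha = row$alpha, eps = base$eps, max_iter = base$max_iter)
}

#' Sweep weight configurations and similarity metrics
#'
#' Runs cross-validation for every configuration of the grid crossed with
#' every metric and selects the combination maximizing the median
#' training-set AUROC averaged across folds. The full sweep table is
#' returned for inspection or persistence.
#'
#' @param grid data.frame from [make_weight_grid()].
#' @param dataset a `treatment_dataset`.
#' @param graph an `msgraph`.
#' @param metrics character vector of similarity metric names.
#' @param seed fold seed passed to [five_fold_cv()].
#' @param n_folds number of folds.
#' @return list with `best_config` (an `edge_weights`), `best_metric`,
#'   `best_score`, and the full `table` (one row per configuration x
#'   metric).
#' @export
weight_sweep <- function(grid, dataset, graph,
                         metrics = c("correlation", "l1"),
                         seed = 1L, n_folds = 5L) {
  if (!nrow(grid)) stop("empty weight grid")
  drugs <- sort(graph$nodes$id[graph$nodes$kind == "drug"])
  diseases <- sort(unique(dataset$disease))
  rows <- list(); best <- -Inf; best_cfg <- NULL; best_metric <- NULL
  for (g in seq_len(nrow(grid))) {
    cfg <- .grid_row_config(grid[g, ])
    profiles <- compute_profiles(graph, cfg, c(drugs, diseases))
    for (m in metrics) {
      cv <- five_fold_cv(graph, dataset, cfg, metric = m, seed = seed,
                         n_folds = n_folds, profiles = profiles)
      score <- unname(cv$training_summary["median_auroc"])
      rows[[length(rows) + 1L]] <-
        cbind(grid[g, , drop = FALSE], metric = m,
              train_median_auroc = score,
              heldout_median_auroc = unname(cv$summary["median_auroc"]))
      if (score > best) {
        best <- score; best_cfg <- cfg; best_metric <- m
      }
    }
  }
  table <- do.call(rbind, rows); rownames(table) <- NULL
  list(best_config = best_cfg, best_metric = best_metric, best_score = best,
       table = table)
}
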