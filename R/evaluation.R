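#' Partition the known associations into cross-validation folds
#'
#' Shuffles the positions of the known associations with a seeded
#' generator, then deals them round-robin into `k` folds, so fold sizes
#' differ by at most one.  Deterministic per seed.
#'
#' @param W an [association_matrix()] with at least `k` known
#'   associations.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return An object of class `fold_plan`: list with `k`, `seed`, `folds`
#'   (list of integer vectors of linear indices into `W$values`).
#' @export
make_folds <- function(W, k = 10L, seed = 1L) {
  stopifnot(inherits(W, "association_matrix"))
  pos <- which(W$values == 1)
  if (length(pos) < k) {
    stop("only ", length(pos), " known associations for ", k, " folds",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample(pos))
  assignment <- rep_len(seq_len(k), length(perm))
  folds <- split(perm, assignment)
  names(folds) <- NULL
  structure(list(k = as.integer(k), seed = as.integer(seed), folds = folds),
            class = "fold_plan")
}

#' Score one cross-validation fold
#'
#' Zeroes the fold's associations out of the training matrix, reruns the
#' full pipeline (composite similarities including the GIP kernel, walk
#' budgets, both walks) from the masked matrix only — so nothing leaks
#' from the held-out pairs — and returns scores and labels for the
#' evaluation set: the held-out positives plus the pairs unknown in the
#' complete matrix.  Training positives are never scored as negatives.
#'
#' @param features_r,features_d [feature_matrix()] objects.
#' @param W the complete [association_matrix()].
#' @param fold integer vector of linear indices (one element of
#'   `fold_plan$folds`).
#' @param config an [ibrw_config()].
#' @return A list with `scores`, `labels` (1 = held-out positive,
#'   0 = unknown pair), and the `fit`.
#' @export
score_fold <- function(features_r, features_d, W, fold,
                       config = ibrw_config()) {
  stopifnot(inherits(W, "association_matrix"))
  train_values <- W$values
  train_values[fold] <- 0
  if (sum(train_values) == 0) {
    stop("fold removes every association; nothing left to train on",
         call. = FALSE)
  }
  train <- association_matrix(W$drug_index, W$disease_index, train_values)
  fit <- ibrw(features_r, features_d, train, config)
  negs <- which(W$values == 0)
  if (config$neg_fraction < 1) {
    n_keep <- max(1L, floor(config$neg_fraction * length(negs)))
    negs <- with_seed(child_seed(config, "negatives"),
                      sort(sample(negs, n_keep)))
  }
  eval_idx <- c(fold, negs)
  list(scores = fit$scores$values[eval_idx],
       labels = c(rep(1L, length(fold)), rep(0L, length(negs))),
       fit = fit)
}

#' Ranking metrics for one score/label vector
#'
#' AUROC uses the rank-sum (Mann-Whitney) formulation, giving tied scores
#' half credit.  AUPR is the step integral of the precision-recall curve
#' (sum of precision times recall increments over descending score
#' cut-points).  Precision, recall, micro-F1 and macro-F1 are computed
#' after binarizing at the observed cut-point that maximizes micro-F1
#' (predict positive when `score >= cut`); ties among cut-points resolve
#' to the largest one.  Micro-F1 is the positive-class F1
#' (`2PR/(P+R)`); macro-F1 is the unweighted mean of the two per-class
#' F1 scores.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length with both classes present.
#' @return A named list: `auroc`, `aupr`, `micro_f1`, `macro_f1`,
#'   `precision`, `recall`, `threshold`.
#' @export
ranking_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("ranking_metrics needs both classes", call. = FALSE)
  }
  r <- rank(scores)  # average ranks: ties get half credit
  auroc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  # group by distinct cut-points, descending
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- labels[ord]
  last_of_group <- which(!duplicated(s_sorted, fromLast = TRUE))
  tp <- cumsum(y_sorted)[last_of_group]
  npred <- last_of_group
  fp <- npred - tp
  prec <- tp / npred
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)

  f1_pos <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  best <- which.max(f1_pos)  # first index = largest cut-point on ties
  threshold <- s_sorted[last_of_group[best]]
  tp_b <- tp[best]; fp_b <- fp[best]
  fn_b <- np - tp_b; tn_b <- nn - fp_b
  precision <- prec[best]
  recall <- rec[best]
  micro_f1 <- f1_pos[best]
  prec_neg <- if (tn_b + fn_b > 0) tn_b / (tn_b + fn_b) else 0
  rec_neg <- tn_b / nn
  f1_neg <- if (prec_neg + rec_neg > 0) {
    2 * prec_neg * rec_neg / (prec_neg + rec_neg)
  } else 0
  list(auroc = auroc, aupr = aupr, micro_f1 = micro_f1,
       macro_f1 = (micro_f1 + f1_neg) / 2,
       precision = precision, recall = recall, threshold = threshold)
}

#' Ten-fold cross-validation of the full pipeline
#'
#' Runs [score_fold()] on every fold of a seeded [make_folds()] plan and
#' aggregates the six ranking metrics as mean and standard deviation.
#'
#' @param features_r,features_d [feature_matrix()] objects.
#' @param W the complete [association_matrix()].
#' @param config an [ibrw_config()].
#' @param k number of folds.
#' @param seed fold seed; defaults to `config$seed`.
#' @return An object of class `metric_report`: `per_fold` (data frame, one
#'   row per fold), `mean`, `sd` (named numeric vectors over the six
#'   metrics), `k`, `seed`.
#' @export
cross_validate <- function(features_r, features_d, W,
                           config = ibrw_config(), k = 10L, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(config, "folds")
  plan <- make_folds(W, k = k, seed = seed)
  metric_names <- c("auroc", "aupr", "micro_f1", "macro_f1",
                    "precision", "recall")
  rows <- lapply(seq_along(plan$folds), function(i) {
    sf <- score_fold(features_r, features_d, W, plan$folds[[i]], config)
    m <- ranking_metrics(sf$scores, sf$labels)
    data.frame(fold = i, as.data.frame(m[c(metric_names, "threshold")]))
  })
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_names]),
                 sd = apply(per_fold[metric_names], 2L, stats::sd),
                 k = plan$k, seed = plan$seed),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", x$k, "-fold cross-validation (seed ", x$seed,
      ")\n", sep = "")
  out <- data.frame(metric = names(x$mean),
                    mean = round(x$mean, 4), sd = round(x$sd, 4))
  print(out, row.names = FALSE)
  invisible(x)
}
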