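#' Symmetric Laplacian normalization of a similarity matrix
#'
#' `S_norm = D^(-1/2) S D^(-1/2)` with `D` the diagonal of row sums.  Rows
#' and columns of zero degree map to all-zero rows/columns (an isolated
#' node propagates nothing).  The result is symmetric with spectral radius
#' at most 1.
#'
#' @param S a [similarity_matrix()].
#' @return A [similarity_matrix()] with stage `"normalized"`.
#' @export
laplacian_normalize <- function(S) {
  stopifnot(inherits(S, "similarity_matrix"))
  d <- rowSums(S$values)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Sn <- S$values * outer(dinv, dinv)
  similarity_matrix(S$index, Sn, stage = "normalized")
}

# Resolve a walk-budget argument (walk_length_vector or single number)
# into per-node floored iteration budgets of length n.
resolve_floors <- function(L, n, kind) {
  if (inherits(L, "walk_length_vector")) {
    if (L$kind != kind) {
      stop("walk length vector is for ", L$kind, "s, expected ", kind, "s",
           call. = FALSE)
    }
    if (length(L$values) != n) {
      stop("walk length vector has wrong length", call. = FALSE)
    }
    L$floored
  } else {
    if (!is.numeric(L) || length(L) != 1L || L < 0) {
      stop("fixed walk length must be a single number >= 0", call. = FALSE)
    }
    rep(floor(L), n)
  }
}

#' Drug-side random walk with restart, gated by per-drug budgets
#'
#' Starting from `F0 = W`, iterates
#' `F_t(i, .) = alpha * F_{t-1}(i, .) %*% S_d + (1 - alpha) * W(i, .)`
#' for every drug whose floored budget still covers iteration `t`
#' (`t <= floor(L_r(i))`); rows past their budget are frozen.  Iteration
#' stops at the largest floored budget, the stopping rule itself — there
#' is no convergence tolerance.
#'
#' @param Sd_norm Laplacian-normalized disease [similarity_matrix()].
#' @param W an [association_matrix()].
#' @param L_r per-drug `walk_length_vector`, or a single fixed length.
#' @param alpha walk weight in (0, 1); `1 - alpha` is the restart mass.
#' @return A [score_matrix()] `F_r`.
#' @export
drug_side_walk <- function(Sd_norm, W, L_r, alpha = 0.1) {
  stopifnot(inherits(Sd_norm, "similarity_matrix"),
            inherits(W, "association_matrix"))
  check_same_index(Sd_norm$index, W$disease_index, "drug_side_walk")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  floors <- resolve_floors(L_r, W$drug_index$size, "drug")
  Fm <- W$values
  t_max <- max(floors, 0)
  t <- 1
  while (t <= t_max) {
    Fn <- alpha * (Fm %*% Sd_norm$values) + (1 - alpha) * W$values
    act <- floors >= t
    Fm[act, ] <- Fn[act, , drop = FALSE]
    t <- t + 1
  }
  score_matrix(W$drug_index, W$disease_index, Fm)
}

#' Disease-side random walk with restart, gated by per-disease budgets
#'
#' Mirror of [drug_side_walk()]: information propagates through the drug
#' similarity network (`F_t(., j) = alpha * S_r %*% F_{t-1}(., j) +
#' (1 - alpha) * W(., j)`), and columns are gated by the per-disease
#' budgets.
#'
#' @param Sr_norm Laplacian-normalized drug [similarity_matrix()].
#' @param W an [association_matrix()].
#' @param L_d per-disease `walk_length_vector`, or a single fixed length.
#' @param alpha walk weight in (0, 1).
#' @return A [score_matrix()] `F_d`.
#' @export
disease_side_walk <- function(Sr_norm, W, L_d, alpha = 0.1) {
  stopifnot(inherits(Sr_norm, "similarity_matrix"),
            inherits(W, "association_matrix"))
  check_same_index(Sr_norm$index, W$drug_index, "disease_side_walk")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  floors <- resolve_floors(L_d, W$disease_index$size, "disease")
  Fm <- W$values
  t_max <- max(floors, 0)
  t <- 1
  while (t <= t_max) {
    Fn <- alpha * (Sr_norm$values %*% Fm) + (1 - alpha) * W$values
    act <- floors >= t
    Fm[, act] <- Fn[, act, drop = FALSE]
    t <- t + 1
  }
  score_matrix(W$drug_index, W$disease_index, Fm)
}

#' Integrate the two walk score matrices
#'
#' `F = (F_r + F_d) / 2`, the final association relevance matrix.
#'
#' @param F_r,F_d [score_matrix()] objects over the same indices.
#' @return A [score_matrix()].
#' @export
integrate_scores <- function(F_r, F_d) {
  stopifnot(inherits(F_r, "score_matrix"), inherits(F_d, "score_matrix"))
  check_same_index(F_r$drug_index, F_d$drug_index, "integrate_scores")
  check_same_index(F_r$disease_index, F_d$disease_index, "integrate_scores")
  score_matrix(F_r$drug_index, F_r$disease_index,
               (F_r$values + F_d$values) / 2)
}

#' Full prediction pipeline
#'
#' Orchestrates the whole method: composite similarities on both sides,
#' per-node walk budgets from the bipartite Jaccard index (or fixed
#' budgets in `mode = "fixed"`), Laplacian normalization, the two gated
#' restart walks, and the final integration.  Deterministic for a given
#' `config$seed`.
#'
#' @param features_r drug [feature_matrix()].
#' @param features_d disease [feature_matrix()].
#' @param W an [association_matrix()] aligned with both feature matrices.
#' @param config an [ibrw_config()].
#' @return An object of class `ibrw_fit`: list with `scores` (integrated
#'   [score_matrix()]), `F_r`, `F_d`, `S_r`, `S_d`, `L_r`, `L_d`, `JI`,
#'   `config`.
#' @export
ibrw <- function(features_r, features_d, W, config = ibrw_config()) {
  stopifnot(inherits(features_r, "feature_matrix"),
            inherits(features_d, "feature_matrix"),
            inherits(W, "association_matrix"),
            inherits(config, "ibrw_config"))
  check_same_index(features_r$index, W$drug_index, "ibrw")
  check_same_index(features_d$index, W$disease_index, "ibrw")

  S_r <- composite_similarity(features_r, W, "drug", config)
  S_d <- composite_similarity(features_d, W, "disease", config)

  JI <- jaccard_bipartite(W)
  L <- walk_lengths(JI, W$drug_index, W$disease_index)
  if (config$mode == "fixed") {
    L_r <- config$fixed_L_r
    L_d <- config$fixed_L_d
  } else {
    L_r <- L$drugs
    L_d <- L$diseases
  }

  Sr_norm <- laplacian_normalize(S_r)
  Sd_norm <- laplacian_normalize(S_d)
  F_r <- drug_side_walk(Sd_norm, W, L_r, alpha = config$alpha)
  F_d <- disease_side_walk(Sr_norm, W, L_d, alpha = config$alpha)
  F <- integrate_scores(F_r, F_d)

  structure(list(scores = F, F_r = F_r, F_d = F_d,
                 S_r = S_r, S_d = S_d,
                 L_r = L$drugs, L_d = L$diseases, JI = JI,
                 config = config),
            class = "ibrw_fit")
}

#' @export
print.ibrw_fit <- function(x, ...) {
  cat("<ibrw_fit> ", x$scores$drug_index$size, " drugs x ",
      x$scores$disease_index$size, " diseases; mode=", x$config$mode,
      ", alpha=", x$config$alpha, "\n", sep = "")
  cat("  walk budgets: drugs max ", max(x$L_r$floored),
      ", diseases max ", max(x$L_d$floored), "\n", sep = "")
  invisible(x)
}
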