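#' Neighbor and two-hop neighbor sets on the bipartite network
#'
#' For each drug, `drug_neighbors` is the set of its associated diseases
#' and `drug_two_hop` the union of the drug sets of those diseases (all
#' drugs reachable in two hops); symmetrically for diseases.  A node with
#' no associations has empty sets throughout.
#'
#' @param W an [association_matrix()].
#' @return A list of class `neighbor_sets` with fields `drug_neighbors`,
#'   `disease_neighbors`, `drug_two_hop`, `disease_two_hop`, each a named
#'   list of character id vectors.
#' @export
neighbor_sets <- function(W) {
  stopifnot(inherits(W, "association_matrix"))
  V <- W$values
  rid <- W$drug_index$ids
  did <- W$disease_index$ids
  drug_neighbors <- lapply(seq_along(rid), function(i) did[V[i, ] == 1])
  disease_neighbors <- lapply(seq_along(did), function(j) rid[V[, j] == 1])
  # two-hop: drugs sharing >= 1 disease with drug i (via counterpart sets)
  RR <- V %*% t(V) > 0
  DD <- t(V) %*% V > 0
  has_r <- rowSums(V) > 0
  has_d <- colSums(V) > 0
  drug_two_hop <- lapply(seq_along(rid), function(i) {
    if (has_r[i]) rid[RR[i, ]] else character(0)
  })
  disease_two_hop <- lapply(seq_along(did), function(j) {
    if (has_d[j]) did[DD[j, ]] else character(0)
  })
  names(drug_neighbors) <- names(drug_two_hop) <- rid
  names(disease_neighbors) <- names(disease_two_hop) <- did
  structure(list(drug_neighbors = drug_neighbors,
                 disease_neighbors = disease_neighbors,
                 drug_two_hop = drug_two_hop,
                 disease_two_hop = disease_two_hop),
            class = "neighbor_sets")
}

#' Jaccard influence index on the bipartite network
#'
#' Because drugs and diseases never share direct neighbors, the classical
#' Jaccard index is computed between a drug's disease set `N_r(i)` and the
#' disease-side two-hop set of the disease,
#' `Nhat_d(j) = union of N_r(c) over drugs c associated with j` (both sets
#' of diseases):
#' `JI(i,j) = |N_r(i) ∩ Nhat_d(j)| / |N_r(i) ∪ Nhat_d(j)|`, with the
#' `0/0 := 0` convention for isolated nodes.
#'
#' @param W an [association_matrix()].
#' @return A numeric `n_r` x `n_d` matrix with entries in `[0, 1]`.
#' @export
jaccard_bipartite <- function(W) {
  stopifnot(inherits(W, "association_matrix"))
  V <- W$values
  # Bd[j, ] indicates Nhat_d(d_j) over diseases
  M <- t(V) %*% V
  Bd <- (M > 0) + 0
  Bd[, colSums(V) == 0] <- 0  # isolated disease: empty two-hop set
  Bd[colSums(V) == 0, ] <- 0
  inter <- V %*% t(Bd)
  sz_r <- rowSums(V)
  sz_d <- rowSums(Bd)
  un <- outer(sz_r, sz_d, `+`) - inter
  JI <- ifelse(un > 0, inter / un, 0)
  dimnames(JI) <- list(W$drug_index$ids, W$disease_index$ids)
  JI
}

#' Per-node walk-length budgets from Jaccard influence
#'
#' A node's walk length is its total influence: the row sum (drugs) or
#' column sum (diseases) of the bipartite Jaccard matrix.  The floored
#' companion is what gates the walk iterations (`t <= floor(L)`), so a
#' budget below 1 means the node never propagates.
#'
#' @param JI bipartite Jaccard matrix from [jaccard_bipartite()].
#' @param drug_index,disease_index optional [entity_index()] objects; taken
#'   from `JI` dimnames when omitted.
#' @return A list with two `walk_length_vector` objects, `drugs` and
#'   `diseases`; each has fields `kind`, `values`, `floored`.
#' @export
walk_lengths <- function(JI, drug_index = NULL, disease_index = NULL) {
  JI <- as.matrix(JI)
  if (any(JI < 0 | JI > 1)) {
    stop("walk_lengths: Jaccard entries must lie in [0, 1]", call. = FALSE)
  }
  mk <- function(kind, values, ids) {
    names(values) <- ids
    structure(list(kind = kind, values = values,
                   floored = floor(values)),
              class = "walk_length_vector")
  }
  rid <- if (!is.null(drug_index)) drug_index$ids else rownames(JI)
  did <- if (!is.null(disease_index)) disease_index$ids else colnames(JI)
  list(drugs = mk("drug", rowSums(JI), rid),
       diseases = mk("disease", colSums(JI), did))
}

#' @export
print.walk_length_vector <- function(x, ...) {
  cat("<walk_length_vector> ", length(x$values), " ", x$kind,
      "s, budgets in [", round(min(x$values), 3), ", ",
      round(max(x$values), 3), "]\n", sep = "")
  invisible(x)
}
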