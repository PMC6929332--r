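# Small fixtures built in code; no files on disk.

tiny_indices <- function(n_r = 2L, n_d = 2L) {
  list(drugs = entity_index(paste0("r", seq_len(n_r)), "drug"),
       diseases = entity_index(paste0("d", seq_len(n_d)), "disease"))
}

tiny_assoc <- function(values) {
  values <- as.matrix(values)
  idx <- tiny_indices(nrow(values), ncol(values))
  association_matrix(idx$drugs, idx$diseases, values)
}

# random binary association matrix with a guaranteed positive
random_assoc <- function(n_r, n_d, p = 0.3) {
  values <- matrix(rbinom(n_r * n_d, 1L, p), n_r, n_d)
  if (sum(values) == 0) values[sample(length(values), 1L)] <- 1
  tiny_assoc(values)
}

random_features <- function(index, n_feat, p = 0.3) {
  feature_matrix(index, matrix(rbinom(index$size * n_feat, 1L, p),
                               index$size, n_feat))
}

random_similarity <- function(n, kind = "drug") {
  idx <- entity_index(paste0(substr(kind, 1, 1), seq_len(n)), kind)
  M <- matrix(runif(n * n), n, n)
  S <- (M + t(M)) / 2
  diag(S) <- 1
  similarity_matrix(idx, S)
}

# scalar per-element recursion oracle for the drug-side walk
oracle_drug_walk <- function(Sd, W, floors, alpha) {
  Fm <- W
  t_max <- max(floors, 0)
  for (t in seq_len(t_max)) {
    Fn <- Fm
    for (i in seq_len(nrow(W))) {
      if (t <= floors[i]) {
        for (j in seq_len(ncol(W))) {
          Fn[i, j] <- alpha * sum(Sd[, j] * Fm[i, ]) + (1 - alpha) * W[i, j]
        }
      }
    }
    Fm <- Fn
  }
  Fm
}

# explicit set-based oracle for the bipartite Jaccard index
oracle_jaccard <- function(W) {
  n_r <- nrow(W); n_d <- ncol(W)
  N_r <- lapply(seq_len(n_r), function(i) which(W[i, ] == 1))
  N_d <- lapply(seq_len(n_d), function(j) which(W[, j] == 1))
  JI <- matrix(0, n_r, n_d)
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_d)) {
      nhat_d <- sort(unique(unlist(lapply(N_d[[j]], function(c) N_r[[c]]))))
      un <- union(N_r[[i]], nhat_d)
      if (length(un) > 0) {
        JI[i, j] <- length(intersect(N_r[[i]], nhat_d)) / length(un)
      }
    }
  }
  JI
}
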