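#' Cosine similarity between binary feature profiles
#'
#' Step 1 of the composite similarity: `S1(i,j) = <x_i, x_j> /
#' (||x_i|| ||x_j||)` over the rows of a binary feature matrix (chemical
#' fingerprints for drugs, symptom profiles for diseases).  Pairs in which
#' either profile is all-zero get similarity 0 rather than a division
#' error.
#'
#' @param features a [feature_matrix()].
#' @return A [similarity_matrix()] with stage `"raw"`, entries in `[0, 1]`.
#' @export
cosine_similarity <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  X <- features$values
  nrm <- sqrt(rowSums(X^2))
  G <- X %*% t(X)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, G / denom, 0)
  S <- pmin(pmax(S, 0), 1)  # clamp fp drift at identical profiles
  similarity_matrix(features$index, S, stage = "raw")
}

# Off-diagonal subrange ids for similarity values: 1..10 for
# (0,0.1],(0.1,0.2],...,(0.9,1]; values <= 0 fall outside every subrange.
similarity_subrange <- function(s) {
  as.integer(cut(s, breaks = seq(0, 1, by = 0.1), include.lowest = FALSE))
}

#' Calibrate the informativeness threshold of raw similarities
#'
#' Partitions the off-diagonal raw similarities into ten subranges
#' `(0,0.1], ..., (0.9,1]` and scores each populated subrange by the mean
#' number of shared association counterparts per pair (for drug pairs: the
#' number of diseases associated with both).  The same statistic is
#' recomputed after randomly permuting the pooled off-diagonal similarity
#' values among the pairs (`n_shuffles` times, averaged), which breaks any
#' similarity/sharing relation and so estimates the no-signal baseline.  A
#' subrange whose observed sharing falls below its shuffled baseline
#' carries no repositioning signal; the returned threshold `x*` is the
#' upper bound of the highest such non-informative subrange — the boundary
#' below which similarities are shrunk and above which they are enlarged
#' by [logistic_adjust()].
#'
#' @param S1 a raw [similarity_matrix()].
#' @param W an [association_matrix()] over the same entities.
#' @param n_shuffles number of permutations for the baseline (>= 1).
#' @param seed RNG seed for the permutations.
#' @return The threshold `x*` in `{0.1, ..., 1.0}`; falls back to `0.1`
#'   with a warning when no subrange qualifies or no pair shares a
#'   counterpart.
#' @export
informative_threshold <- function(S1, W, n_shuffles = 20L, seed = 1L) {
  stopifnot(inherits(S1, "similarity_matrix"),
            inherits(W, "association_matrix"), n_shuffles >= 1L)
  kind <- S1$index$kind
  if (kind == "drug") {
    check_same_index(S1$index, W$drug_index, "informative_threshold")
    shared_counts <- W$values %*% t(W$values)
  } else {
    check_same_index(S1$index, W$disease_index, "informative_threshold")
    shared_counts <- t(W$values) %*% W$values
  }
  ut <- upper.tri(S1$values)
  s <- S1$values[ut]
  shared <- shared_counts[ut]
  if (!any(shared > 0)) {
    warning("no entity pair shares an association; ",
            "falling back to threshold 0.1", call. = FALSE)
    return(0.1)
  }
  bins <- similarity_subrange(s)
  bin_mean <- function(b) {
    out <- rep(NA_real_, 10L)
    m <- tapply(shared[!is.na(b)], b[!is.na(b)], mean)
    out[as.integer(names(m))] <- m
    out
  }
  obs_mean <- bin_mean(bins)

  shuf_sum <- shuf_n <- numeric(10L)
  with_seed(seed, {
    for (r in seq_len(n_shuffles)) {
      bp <- similarity_subrange(sample(s))
      keep <- !is.na(bp)
      a <- tapply(shared[keep], bp[keep], sum)
      k <- tapply(shared[keep], bp[keep], length)
      shuf_sum[as.integer(names(a))] <- shuf_sum[as.integer(names(a))] + a
      shuf_n[as.integer(names(k))] <- shuf_n[as.integer(names(k))] + k
    }
  })
  shuf_mean <- ifelse(shuf_n > 0, shuf_sum / shuf_n, NA_real_)

  qualifies <- which(!is.na(obs_mean) & !is.na(shuf_mean) &
                       obs_mean < shuf_mean)
  if (length(qualifies) == 0L) {
    warning("no non-informative subrange found; ",
            "falling back to threshold 0.1", call. = FALSE)
    return(0.1)
  }
  max(qualifies) / 10
}

#' Logistic adjustment of raw similarities
#'
#' Step 2: shrinks similarities below the informativeness threshold `x*`
#' towards 0 and enlarges those above it, via
#' `S2 = 1 / (1 + exp(c_eff * S1 + d))` with effective steepness
#' `c_eff = -d / x*`.  This parametrization makes the map strictly
#' increasing, anchors `S2(0) = 1/(1+e^d)` (0.001 at the default
#' `d = log(999)`) and puts the midpoint `S2(x*) = 0.5` exactly at the
#' threshold.  The diagonal is forced to 1 after the transform.
#'
#' @param S1 a [similarity_matrix()] with entries in `[0, 1]`.
#' @param x_star threshold in (0, 1].
#' @param d logistic offset, > 0.
#' @return A [similarity_matrix()] with stage `"adjusted"`.
#' @export
logistic_adjust <- function(S1, x_star, d = log(999)) {
  stopifnot(inherits(S1, "similarity_matrix"))
  if (!is.numeric(x_star) || x_star <= 0) {
    stop("x_star must be > 0", call. = FALSE)
  }
  if (d <= 0) stop("d must be > 0", call. = FALSE)
  c_eff <- -d / x_star
  S2 <- 1 / (1 + exp(c_eff * S1$values + d))
  diag(S2) <- 1
  similarity_matrix(S1$index, S2, stage = "adjusted")
}

#' Association-sharing graph over one node kind
#'
#' Step 3 substrate: a weighted undirected graph whose nodes are the drugs
#' (or diseases) and whose edge weight between two nodes is the number of
#' counterpart entities associated with both.  Pairs sharing nothing have
#' no edge.
#'
#' @param W an [association_matrix()].
#' @param kind `"drug"` or `"disease"`.
#' @return An [igraph::graph] with vertex names and a `weight` edge
#'   attribute.
#' @export
sharing_graph <- function(W, kind = c("drug", "disease")) {
  kind <- match.arg(kind)
  stopifnot(inherits(W, "association_matrix"))
  if (kind == "drug") {
    C <- W$values %*% t(W$values)
    ids <- W$drug_index$ids
  } else {
    C <- t(W$values) %*% W$values
    ids <- W$disease_index$ids
  }
  diag(C) <- 0
  dimnames(C) <- list(ids, ids)
  igraph::graph_from_adjacency_matrix(C, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Cohesiveness f(C) = W_in / (W_in + W_bound + penalty * |C|) from the
# weighted adjacency matrix A and a logical membership vector.
cohesiveness <- function(A, members, penalty) {
  deg <- rowSums(A)
  win <- sum(A[members, members, drop = FALSE]) / 2
  wbound <- sum(deg[members]) - 2 * win
  denom <- win + wbound + penalty * sum(members)
  if (denom <= 0) 0 else win / denom
}

#' Greedy overlapping clustering by cohesiveness
#'
#' A ClusterONE-style grower on the association-sharing graph.  Seeds are
#' taken at the unclaimed node of highest weighted degree; the cluster is
#' modified by the single node addition or removal that most increases the
#' cohesiveness `f(C) = W_in / (W_in + W_bound + P(C))`, with per-node
#' penalty `P(C) = penalty_per_node * |C|`, until no step improves it.
#' Cluster pairs whose overlap score `|A∩B|^2 / (|A||B|)` exceeds
#' `overlap_threshold` are merged, and clusters below `min_size` are
#' discarded.  All tie-breaks are by node/id order, so the procedure is
#' deterministic.
#'
#' @param g a weighted graph from [sharing_graph()].
#' @param penalty_per_node nonnegative penalty per cluster member.
#' @param min_size minimum retained cluster size (>= 2).
#' @param overlap_threshold merge threshold in (0, 1].
#' @param seed accepted for interface uniformity; the grower itself is
#'   deterministic.
#' @return An object of class `cluster_set`: list with `clusters` (each a
#'   list with `members`, `f`) and `penalty_per_node`.
#' @export
cluster_one <- function(g, penalty_per_node = 2, min_size = 2L,
                        overlap_threshold = 0.8, seed = 1L) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  empty <- structure(list(clusters = list(),
                          penalty_per_node = penalty_per_node),
                     class = "cluster_set")
  if (n == 0L || igraph::ecount(g) == 0L) return(empty)
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  dimnames(A) <- list(ids, ids)
  deg <- rowSums(A)

  # incremental grower: win/wbound/conn are updated in O(n) per step, where
  # conn[v] is the total edge weight between node v and the current cluster
  grow <- function(seed_node) {
    members <- rep(FALSE, n)
    members[seed_node] <- TRUE
    conn <- A[, seed_node]
    win <- 0
    wbound <- deg[seed_node]
    f_of <- function(w_in, w_bd, size) {  # vectorized over candidates
      denom <- w_in + w_bd + penalty_per_node * size
      ifelse(denom <= 0, 0, w_in / denom)
    }
    f <- f_of(win, wbound, 1L)
    repeat {
      size <- sum(members)
      adds <- which(!members & conn > 0)
      f_add <- if (length(adds) > 0L) {
        f_of(win + conn[adds], wbound + deg[adds] - 2 * conn[adds], size + 1L)
      } else numeric(0)
      rems <- if (size > 1L) which(members) else integer(0)
      f_rem <- if (length(rems) > 0L) {
        f_of(win - conn[rems], wbound - deg[rems] + 2 * conn[rems], size - 1L)
      } else numeric(0)
      best_add <- if (length(f_add) > 0L) max(f_add) else -Inf
      best_rem <- if (length(f_rem) > 0L) max(f_rem) else -Inf
      best <- max(best_add, best_rem)
      if (best <= f + 1e-12) break
      if (best_add >= best_rem) {  # prefer growth on ties
        v <- adds[which.max(f_add)]
        win <- win + conn[v]
        wbound <- wbound + deg[v] - 2 * conn[v]
        members[v] <- TRUE
        conn <- conn + A[, v]
      } else {
        u <- rems[which.max(f_rem)]
        win <- win - conn[u]
        wbound <- wbound - deg[u] + 2 * conn[u]
        members[u] <- FALSE
        conn <- conn - A[, u]
      }
      f <- f_of(win, wbound, sum(members))
    }
    members
  }

  unclaimed <- rep(TRUE, n)
  unclaimed[deg == 0] <- FALSE
  member_sets <- list()
  while (any(unclaimed)) {
    cand <- which(unclaimed)
    seed_node <- cand[order(-deg[cand], ids[cand])][1L]
    members <- grow(seed_node)
    member_sets[[length(member_sets) + 1L]] <- which(members)
    unclaimed[members] <- FALSE
    unclaimed[seed_node] <- FALSE
  }

  # merge heavily overlapping clusters
  repeat {
    merged <- FALSE
    k <- length(member_sets)
    if (k < 2L) break
    for (a in seq_len(k - 1L)) {
      for (b in seq((a + 1L), k)) {
        ov <- length(intersect(member_sets[[a]], member_sets[[b]]))^2 /
          (length(member_sets[[a]]) * length(member_sets[[b]]))
        if (ov > overlap_threshold) {
          member_sets[[a]] <- sort(union(member_sets[[a]], member_sets[[b]]))
          member_sets[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  keep <- vapply(member_sets, length, 1L) >= min_size
  member_sets <- member_sets[keep]
  clusters <- lapply(member_sets, function(idx) {
    members <- rep(FALSE, n); members[idx] <- TRUE
    list(members = ids[idx],
         f = cohesiveness(A, members, penalty_per_node))
  })
  structure(list(clusters = clusters, penalty_per_node = penalty_per_node),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", length(x$clusters), " clusters, penalty ",
      x$penalty_per_node, "/node\n", sep = "")
  invisible(x)
}

#' Boost similarities of co-clustered pairs
#'
#' Step 3: a pair co-occurring in at least one cluster has its adjusted
#' similarity multiplied by `(1 + f)`, where `f` is the largest
#' cohesiveness among the clusters the pair shares; all other entries
#' (including the diagonal) are unchanged.
#'
#' @param S2 an adjusted [similarity_matrix()] with entries in `[0, 1]`.
#' @param clusters a `cluster_set` from [cluster_one()].
#' @return A [similarity_matrix()] with stage `"boosted"`, entries in
#'   `[0, 2]`.
#' @export
cluster_boost <- function(S2, clusters) {
  stopifnot(inherits(S2, "similarity_matrix"),
            inherits(clusters, "cluster_set"))
  n <- S2$index$size
  B <- matrix(1, n, n)
  for (cl in clusters$clusters) {
    idx <- match(cl$members, S2$index$ids)
    if (anyNA(idx)) {
      stop("cluster member not present in the similarity index",
           call. = FALSE)
    }
    B[idx, idx] <- pmax(B[idx, idx], 1 + cl$f)
  }
  diag(B) <- 1
  similarity_matrix(S2$index, S2$values * B, stage = "boosted")
}

#' Gaussian interaction profile kernel similarity
#'
#' Step 4: each drug's interaction profile is its row of the association
#' matrix (each disease's, its column); similarity between two profiles is
#' `exp(-gamma * ||IP_i - IP_j||^2)` with bandwidth
#' `gamma = gamma_tilde / mean(||IP||^2)`.
#'
#' @param W an [association_matrix()] with at least one association.
#' @param kind `"drug"` or `"disease"`.
#' @param gamma_tilde bandwidth numerator, > 0 (default 1).
#' @return A [similarity_matrix()] with stage `"gip"`, entries in
#'   `(0, 1]`, unit diagonal.
#' @export
gip_kernel <- function(W, kind = c("drug", "disease"), gamma_tilde = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(W, "association_matrix"), gamma_tilde > 0)
  P <- if (kind == "drug") W$values else t(W$values)
  index <- if (kind == "drug") W$drug_index else W$disease_index
  sq <- rowSums(P^2)
  if (mean(sq) == 0) {
    stop("GIP undefined: no associations", call. = FALSE)
  }
  gamma <- gamma_tilde / mean(sq)
  D2 <- outer(sq, sq, `+`) - 2 * P %*% t(P)
  D2 <- pmax(D2, 0)
  K <- exp(-gamma * D2)
  diag(K) <- 1
  similarity_matrix(index, K, stage = "gip")
}

#' Average the boosted and kernel similarities
#'
#' Final combination step: `S = (S3 + S_KR) / 2`.
#'
#' @param S3 boosted [similarity_matrix()].
#' @param Skr GIP-kernel [similarity_matrix()] over the same index.
#' @return A [similarity_matrix()] with stage `"composite"`.
#' @export
combine_similarity <- function(S3, Skr) {
  stopifnot(inherits(S3, "similarity_matrix"),
            inherits(Skr, "similarity_matrix"))
  check_same_index(S3$index, Skr$index, "combine_similarity")
  similarity_matrix(S3$index, (S3$values + Skr$values) / 2,
                    stage = "composite")
}

#' Composite similarity pipeline for one node kind
#'
#' Chains the four similarity stages: cosine on feature profiles,
#' shuffle-calibrated logistic adjustment, cohesiveness cluster boost on
#' the association-sharing graph, and averaging with the Gaussian
#' interaction profile kernel.  Stage toggles in `config` reproduce the
#' leave-one-stage-out variants; with stage 4 disabled the result is the
#' boosted matrix, with stage 2 disabled the raw cosine feeds stage 3
#' directly.  The diagonal is forced to 1 at every stage.
#'
#' @param features a [feature_matrix()] for this node kind.
#' @param W an [association_matrix()] over both kinds.
#' @param kind `"drug"` or `"disease"`.
#' @param config an [ibrw_config()].
#' @return A [similarity_matrix()]; the calibrated threshold and the
#'   cluster set are attached as attribute `"details"`.
#' @export
composite_similarity <- function(features, W, kind = c("drug", "disease"),
                                 config = ibrw_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(features, "feature_matrix"),
            inherits(config, "ibrw_config"))
  widx <- if (kind == "drug") W$drug_index else W$disease_index
  check_same_index(features$index, widx, "composite_similarity")

  S1 <- cosine_similarity(features)
  S1 <- similarity_matrix(S1$index, `diag<-`(S1$values, 1), stage = "raw")

  x_star <- NULL
  if (config$step2_enabled) {
    x_star <- config$x_star
    if (is.null(x_star)) {
      x_star <- informative_threshold(
        S1, W, n_shuffles = config$shuffles,
        seed = child_seed(config, paste0("threshold_", kind)))
    }
    S2 <- logistic_adjust(S1, x_star, d = config$logistic_d)
  } else {
    S2 <- similarity_matrix(S1$index, S1$values, stage = "adjusted")
  }

  clusters <- NULL
  if (config$step3_enabled) {
    g <- sharing_graph(W, kind)
    clusters <- cluster_one(g, penalty_per_node = config$clusterone_penalty,
                            min_size = config$clusterone_min_size,
                            overlap_threshold = config$clusterone_overlap,
                            seed = child_seed(config, paste0("cluster_", kind)))
    S3 <- cluster_boost(S2, clusters)
  } else {
    S3 <- similarity_matrix(S2$index, S2$values, stage = "boosted")
  }

  if (config$step4_enabled) {
    Skr <- gip_kernel(W, kind, gamma_tilde = config$gip_gamma_tilde)
    S <- combine_similarity(S3, Skr)
  } else {
    S <- similarity_matrix(S3$index, S3$values, stage = "composite")
  }
  attr(S, "details") <- list(x_star = x_star, clusters = clusters)
  S
}
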