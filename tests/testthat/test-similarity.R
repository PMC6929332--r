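test_that("cosine_similarity matches hand-computed cases", {
  idx <- entity_index(c("r1", "r2", "r3", "r4"), "drug")
  X <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 0), c(0, 0, 0))
  S <- cosine_similarity(feature_matrix(idx, X))
  expect_equal(S$values["r1", "r2"], 0.5)     # dot 1, norms sqrt(2)*sqrt(2)
  expect_equal(S$values["r2", "r3"], 0)       # orthogonal
  expect_equal(S$values["r1", "r1"], 1)       # identical nonzero rows
  expect_equal(unname(S$values["r4", ]), rep(0, 4))  # zero row convention
  expect_true(all(S$values >= 0 & S$values <= 1))
})

test_that("informative_threshold recovers a planted boundary", {
  # low-similarity pairs never share a disease, high-similarity pairs
  # always do; the boundary subrange is (0.4,0.5]
  n <- 12L
  idx <- entity_index(sprintf("r%02d", 1:n), "drug")
  didx <- entity_index(sprintf("d%02d", 1:6), "disease")
  S <- matrix(0, n, n)
  W <- matrix(0, n, 6)
  set.seed(11)
  # first 6 drugs: pairwise high similarity, all share disease d1
  hi <- 1:6; lo <- 7:12
  S[hi, hi] <- runif(36, 0.75, 0.95)
  W[hi, 1] <- 1
  # remaining pairs: low similarity, no shared diseases (distinct columns)
  S[lo, lo] <- runif(36, 0.15, 0.45)
  S[hi, lo] <- runif(36, 0.15, 0.45)
  S[lo, hi] <- 0  # symmetrized below
  S <- pmax(S, t(S)); diag(S) <- 1
  W[cbind(7:11, 2:6)] <- 1
  S1 <- similarity_matrix(idx, S, "raw")
  Wm <- association_matrix(idx, didx, W)
  expect_equal(informative_threshold(S1, Wm, n_shuffles = 20, seed = 3), 0.5)
})

test_that("informative_threshold degenerate inputs fall back to 0.1", {
  idx <- tiny_indices(4, 3)
  S1 <- cosine_similarity(random_features(idx$drugs, 10))
  W0 <- association_matrix(idx$drugs, idx$diseases, matrix(0, 4, 3))
  expect_warning(x <- informative_threshold(S1, W0, 5, 1), "falling back")
  expect_equal(x, 0.1)
})

test_that("informative_threshold is invariant to entity ordering", {
  set.seed(21)
  idx <- entity_index(sprintf("r%02d", 1:10), "drug")
  didx <- entity_index(sprintf("d%02d", 1:8), "disease")
  X <- matrix(rbinom(10 * 20, 1, 0.4), 10, 20)
  W <- matrix(rbinom(10 * 8, 1, 0.3), 10, 8)
  S1 <- cosine_similarity(feature_matrix(idx, X))
  Wm <- association_matrix(idx, didx, W)
  x1 <- suppressWarnings(informative_threshold(S1, Wm, 10, 5))
  perm <- sample(10)
  idx_p <- entity_index(idx$ids[perm], "drug")
  S1p <- cosine_similarity(feature_matrix(idx_p, X[perm, ]))
  Wp <- association_matrix(idx_p, didx, W[perm, ])
  x2 <- suppressWarnings(informative_threshold(S1p, Wp, 10, 5))
  expect_equal(x1, x2)
})

test_that("logistic_adjust anchors, midpoint, and monotonicity", {
  idx <- entity_index(c("a", "b", "c"), "drug")
  x_star <- 0.4
  S1 <- similarity_matrix(idx, matrix(c(1, 0, x_star,
                                        0, 1, 0.9,
                                        x_star, 0.9, 1), 3, 3), "raw")
  S2 <- logistic_adjust(S1, x_star)
  expect_equal(S2$values["a", "b"], 1 / (1 + 999))     # S1 = 0 -> 0.001
  expect_equal(S2$values["a", "c"], 0.5)               # S1 = x* -> 0.5
  expect_equal(diag(S2$values), c(a = 1, b = 1, c = 1))
  expect_error(logistic_adjust(S1, 0), "x_star")

  # order preservation on random matrices
  set.seed(4)
  for (rep in 1:10) {
    S <- random_similarity(8)
    adj <- logistic_adjust(S, x_star = runif(1, 0.1, 1))
    ut <- upper.tri(S$values)
    expect_equal(order(S$values[ut]), order(adj$values[ut]))
  }
})

test_that("sharing_graph counts common counterparts", {
  W <- tiny_assoc(rbind(c(1, 1), c(0, 1)))
  g <- sharing_graph(W, "drug")
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::as_data_frame(g)
  expect_equal(sort(c(e$from, e$to)), c("r1", "r2"))
  expect_equal(e$weight, 1)  # shared d2

  # disjoint columns -> empty edge set
  Wd <- tiny_assoc(rbind(c(1, 0), c(0, 1)))
  expect_equal(igraph::ecount(sharing_graph(Wd, "drug")), 0)

  # brute-force oracle agreement on random 10x8 inputs
  set.seed(7)
  for (rep in 1:5) {
    W <- random_assoc(10, 8)
    for (kind in c("drug", "disease")) {
      V <- if (kind == "drug") W$values else t(W$values)
      n <- nrow(V)
      counts <- matrix(0, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j) counts[i, j] <- sum(V[i, ] == 1 & V[j, ] == 1)
      }
      g <- sharing_graph(W, kind)
      A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
      expect_equal(unname(A), counts)
    }
  }
})

test_that("cluster_one finds disconnected cliques with unit cohesiveness", {
  # two disconnected triangles, all weights 1, penalty 0
  A <- matrix(0, 6, 6)
  tri <- function(i) cbind(i[c(1, 1, 2)], i[c(2, 3, 3)])
  A[tri(1:3)] <- 1; A[tri(4:6)] <- 1
  A <- A + t(A)
  dimnames(A) <- list(letters[1:6], letters[1:6])
  g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
  cs <- cluster_one(g, penalty_per_node = 0)
  expect_equal(length(cs$clusters), 2L)
  expect_setequal(lapply(cs$clusters, `[[`, "members"),
                  list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(vapply(cs$clusters, `[[`, 1, "f"), c(1, 1))  # 3/(3+0+0)

  # empty graph -> empty cluster set
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(length(cluster_one(g0)$clusters), 0L)

  # positive penalty never increases cohesiveness
  cs_pen <- cluster_one(g, penalty_per_node = 1)
  for (cl in cs_pen$clusters) expect_lte(cl$f, 1)
})

test_that("cohesiveness arithmetic matches its definition", {
  # square with a diagonal: inside the 3-cycle {1,2,3}, W_in=4, W_bound=4
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- 2  # W_in = 6 over members 1:3
  A[3, 4] <- 4; A[1, 5] <- 2          # boundary = 6
  A <- A + t(A)
  members <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  f <- ibrw:::cohesiveness(A, members, penalty = 0)
  expect_equal(f, 6 / (6 + 6))
})

test_that("cluster_boost multiplies co-clustered pairs by (1 + f_max)", {
  idx <- entity_index(c("a", "b", "c"), "drug")
  S2 <- similarity_matrix(idx, matrix(c(1, 0.4, 0.3,
                                        0.4, 1, 0.2,
                                        0.3, 0.2, 1), 3, 3), "adjusted")
  cs <- structure(list(clusters = list(
    list(members = c("a", "b"), f = 1.0),
    list(members = c("a", "b", "c"), f = 0.25)),
    penalty_per_node = 2), class = "cluster_set")
  S3 <- cluster_boost(S2, cs)
  expect_equal(S3$values["a", "b"], 0.8)        # (1 + max(1, 0.25)) * 0.4
  expect_equal(S3$values["a", "c"], 0.375)      # (1 + 0.25) * 0.3
  expect_equal(S3$values["b", "c"], 0.25)       # (1 + 0.25) * 0.2
  expect_equal(diag(S3$values), c(a = 1, b = 1, c = 1))
  expect_true(all(S3$values >= S2$values))      # boost never decreases
  expect_equal(S3$values, t(S3$values))

  # pair in no cluster unchanged
  none <- structure(list(clusters = list(), penalty_per_node = 2),
                    class = "cluster_set")
  expect_equal(cluster_boost(S2, none)$values, S2$values)
})

test_that("gip_kernel matches the hand-evaluated 2x2 case", {
  W <- tiny_assoc(diag(2))
  K <- gip_kernel(W, "drug", gamma_tilde = 1)
  # profiles (1,0) and (0,1): gamma = 1/((1+1)/2) = 1, dist^2 = 2
  expect_equal(K$values["r1", "r2"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(K$values), c(r1 = 1, r2 = 1))

  # identical profiles -> 1
  Wi <- tiny_assoc(rbind(c(1, 0), c(1, 0)))
  expect_equal(gip_kernel(Wi, "drug")$values["r1", "r2"], 1)

  # doubling gamma_tilde squares every off-diagonal entry
  set.seed(9)
  W <- random_assoc(8, 6)
  K1 <- gip_kernel(W, "disease", gamma_tilde = 1)$values
  K2 <- gip_kernel(W, "disease", gamma_tilde = 2)$values
  expect_equal(K2, K1^2, tolerance = 1e-12)

  # all-zero matrix is an error
  W0 <- tiny_assoc(matrix(0, 2, 2))
  expect_error(gip_kernel(W0, "drug"), "GIP undefined")
})

test_that("gip_kernel agrees with a naive double loop on random input", {
  set.seed(13)
  W <- random_assoc(10, 8)
  K <- gip_kernel(W, "drug", gamma_tilde = 1.5)$values
  P <- W$values
  gamma <- 1.5 / mean(rowSums(P^2))
  for (i in 1:10) for (j in 1:10) {
    expect_equal(K[i, j], exp(-gamma * sum((P[i, ] - P[j, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("combine_similarity is the arithmetic mean", {
  idx <- entity_index(c("a", "b"), "drug")
  S3 <- similarity_matrix(idx, matrix(c(1, 0.8, 0.8, 1), 2, 2), "boosted")
  Skr <- similarity_matrix(idx, matrix(c(1, 0.2, 0.2, 1), 2, 2), "gip")
  S <- combine_similarity(S3, Skr)
  expect_equal(S$values["a", "b"], 0.5)
  expect_equal(combine_similarity(S3, S3)$values, S3$values)
  other <- similarity_matrix(entity_index(c("x", "y"), "drug"), diag(2))
  expect_error(combine_similarity(S3, other), "mismatch")
})

test_that("composite_similarity equals manual composition of its stages", {
  set.seed(31)
  sim <- synth_generate(synth_config(n_r = 20, n_d = 15, seed = 5))
  W <- sim$observed
  cfg <- ibrw_config(seed = 5)
  S <- composite_similarity(sim$drug_features, W, "drug", cfg)

  S1 <- cosine_similarity(sim$drug_features)
  S1 <- similarity_matrix(S1$index, `diag<-`(S1$values, 1), "raw")
  xs <- suppressWarnings(
    informative_threshold(S1, W, cfg$shuffles, cfg$seed + 101L))
  S2 <- logistic_adjust(S1, xs, cfg$logistic_d)
  cl <- cluster_one(sharing_graph(W, "drug"),
                    penalty_per_node = cfg$clusterone_penalty,
                    min_size = cfg$clusterone_min_size,
                    overlap_threshold = cfg$clusterone_overlap)
  S3 <- cluster_boost(S2, cl)
  Skr <- gip_kernel(W, "drug", cfg$gip_gamma_tilde)
  manual <- combine_similarity(S3, Skr)
  expect_equal(S$values, manual$values, tolerance = 1e-12)
  expect_equal(attr(S, "details")$x_star, xs)

  # step toggles
  cfg1 <- ibrw_config(seed = 5, step2_enabled = FALSE,
                      step3_enabled = FALSE, step4_enabled = FALSE)
  S_only1 <- composite_similarity(sim$drug_features, W, "drug", cfg1)
  expect_equal(S_only1$values, S1$values)

  cfg134 <- ibrw_config(seed = 5, step2_enabled = FALSE)
  S134 <- composite_similarity(sim$drug_features, W, "drug", cfg134)
  S3_alt <- cluster_boost(similarity_matrix(S1$index, S1$values, "adjusted"),
                          cl)
  expect_equal(S134$values, combine_similarity(S3_alt, Skr)$values,
               tolerance = 1e-12)

  cfg123 <- ibrw_config(seed = 5, step4_enabled = FALSE)
  S123 <- composite_similarity(sim$drug_features, W, "drug", cfg123)
  expect_equal(S123$values, S3$values, tolerance = 1e-12)
})

test_that("every similarity stage is symmetric, nonnegative, bounded", {
  set.seed(17)
  sim <- synth_generate(synth_config(n_r = 15, n_d = 12, seed = 3))
  cfg <- ibrw_config(seed = 3)
  for (kind in c("drug", "disease")) {
    feats <- if (kind == "drug") sim$drug_features else sim$disease_features
    S <- suppressWarnings(
      composite_similarity(feats, sim$observed, kind, cfg))
    expect_lte(max(abs(S$values - t(S$values))), 1e-9)
    expect_gte(min(S$values), 0)
    expect_lte(max(S$values), 1.5)  # (S3 <= 2) / 2 + (Skr <= 1) / 2
  }
})
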