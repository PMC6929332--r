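#' Bipartite block-adjacency graph of the heterogeneous network
#'
#' An unweighted undirected graph on all `n_r + n_d` nodes whose edges are
#' exactly the known drug-disease associations; same-kind blocks carry no
#' direct edges, so every drug-drug or disease-disease distance arises
#' through bipartite paths (and is therefore even when finite).
#'
#' @param W an [association_matrix()].
#' @return An [igraph::graph] with vertex attributes `name` and `kind`.
#' @export
block_adjacency <- function(W) {
  stopifnot(inherits(W, "association_matrix"))
  n_r <- W$drug_index$size
  n_d <- W$disease_index$size
  idx <- which(W$values == 1, arr.ind = TRUE)
  edges <- rbind(idx[, 1L], n_r + idx[, 2L])
  g <- igraph::make_empty_graph(n = n_r + n_d, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, as.vector(edges))
  igraph::V(g)$name <- c(W$drug_index$ids, W$disease_index$ids)
  igraph::V(g)$kind <- c(rep("drug", n_r), rep("disease", n_d))
  g
}

#' Shortest-path summary of the bipartite network
#'
#' Hop-count shortest paths between all nodes (drugs and diseases pooled;
#' `Inf` for disconnected pairs), plus the per-node eccentricity towards
#' the other kind: `P_r(i)` is the largest finite shortest path from drug
#' `i` to any disease (`P_d(j)` symmetrically).  A node with no finite
#' path to any counterpart gets `P = 0` with a warning.
#'
#' @param W an [association_matrix()].
#' @return A list of class `path_summary` with fields `SP`
#'   (`(n_r+n_d)` square matrix), `P_r`, `P_d`, `drug_ids`, `disease_ids`.
#' @export
shortest_path_summary <- function(W) {
  stopifnot(inherits(W, "association_matrix"))
  g <- block_adjacency(W)
  SP <- igraph::distances(g, algorithm = "unweighted")
  n_r <- W$drug_index$size
  ri <- seq_len(n_r)
  di <- n_r + seq_len(W$disease_index$size)
  max_finite <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) NA_real_ else max(x)
  }
  P_r <- apply(SP[ri, di, drop = FALSE], 1L, max_finite)
  P_d <- apply(SP[ri, di, drop = FALSE], 2L, max_finite)
  if (anyNA(P_r) || anyNA(P_d)) {
    warning("isolated node(s) with no finite path to the other kind; ",
            "their P is reported as 0", call. = FALSE)
    P_r[is.na(P_r)] <- 0
    P_d[is.na(P_d)] <- 0
  }
  names(P_r) <- W$drug_index$ids
  names(P_d) <- W$disease_index$ids
  structure(list(SP = SP, P_r = P_r, P_d = P_d,
                 drug_ids = W$drug_index$ids,
                 disease_ids = W$disease_index$ids),
            class = "path_summary")
}

#' Walk-length versus shortest-path margin report
#'
#' Per node, the margin is `|P - L|`: the absolute difference between the
#' maximum finite shortest path to the other kind and the quantified walk
#' budget.  Reports the fraction of nodes with margin at most 1 (pooled
#' over drugs and diseases, and per kind) plus a margin histogram.
#'
#' @param paths a `path_summary` from [shortest_path_summary()].
#' @param L_r,L_d `walk_length_vector` objects from [walk_lengths()].
#' @return A list of class `margin_report`: `fraction_le1` (pooled),
#'   `fraction_le1_drugs`, `fraction_le1_diseases`, `margins_r`,
#'   `margins_d`, and `histogram` (data frame of margin bins and counts).
#' @export
margin_report <- function(paths, L_r, L_d) {
  stopifnot(inherits(paths, "path_summary"),
            inherits(L_r, "walk_length_vector"),
            inherits(L_d, "walk_length_vector"))
  if (length(L_r$values) != length(paths$P_r) ||
      length(L_d$values) != length(paths$P_d)) {
    stop("margin_report: walk-length vectors do not match the path summary",
         call. = FALSE)
  }
  margins_r <- abs(paths$P_r - L_r$values)
  margins_d <- abs(paths$P_d - L_d$values)
  pooled <- c(margins_r, margins_d)
  breaks <- c(seq(0, max(5, ceiling(max(pooled)))), Inf)
  h <- table(cut(pooled, breaks = breaks, include.lowest = TRUE,
                 right = TRUE))
  structure(list(fraction_le1 = mean(pooled <= 1),
                 fraction_le1_drugs = mean(margins_r <= 1),
                 fraction_le1_diseases = mean(margins_d <= 1),
                 margins_r = margins_r, margins_d = margins_d,
                 histogram = data.frame(bin = names(h),
                                        count = as.integer(h))),
            class = "margin_report")
}

#' @export
print.margin_report <- function(x, ...) {
  cat("<margin_report> fraction of nodes with |P - L| <= 1: ",
      round(x$fraction_le1, 3), " (drugs ",
      round(x$fraction_le1_drugs, 3), ", diseases ",
      round(x$fraction_le1_diseases, 3), ")\n", sep = "")
  invisible(x)
}

#' Mean shortest path per similarity subrange
#'
#' Partitions the same-kind off-diagonal pairs with finite shortest paths
#' by similarity subrange `(0,0.1], ..., (0.9,1]` (composite similarities
#' above 1 are pooled into the top subrange) and reports the mean
#' shortest-path length per populated subrange, together with the Spearman
#' rank correlation between subrange index and mean path.  Under
#' guilt-by-association the correlation is expected to be negative: more
#' similar nodes sit closer in the bipartite network.
#'
#' @param S a same-kind [similarity_matrix()].
#' @param SP_block the matching same-kind submatrix of `path_summary$SP`.
#' @return A list of class `similarity_distance_profile`: `table` (data
#'   frame with `subrange`, `n_pairs`, `mean_shortest_path`; unpopulated
#'   subranges have `n_pairs = 0` and `NA` mean) and `correlation`
#'   (`NA` when fewer than two subranges are populated).
#' @export
similarity_distance_profile <- function(S, SP_block) {
  stopifnot(inherits(S, "similarity_matrix"))
  SP_block <- as.matrix(SP_block)
  if (!all(dim(SP_block) == S$index$size)) {
    stop("similarity_distance_profile: shortest-path block has wrong shape",
         call. = FALSE)
  }
  ut <- upper.tri(S$values)
  s <- S$values[ut]
  sp <- SP_block[ut]
  keep <- is.finite(sp) & s > 0
  bins <- similarity_subrange(pmin(s[keep], 1))
  mean_sp <- rep(NA_real_, 10L)
  n_pairs <- rep(0L, 10L)
  if (any(keep)) {
    m <- tapply(sp[keep], bins, mean)
    k <- tapply(sp[keep], bins, length)
    mean_sp[as.integer(names(m))] <- m
    n_pairs[as.integer(names(k))] <- k
  }
  pop <- which(n_pairs > 0L)
  correlation <- if (length(pop) >= 2L && stats::sd(mean_sp[pop]) > 0) {
    suppressWarnings(stats::cor(pop, mean_sp[pop], method = "spearman"))
  } else {
    NA_real_
  }
  labels <- sprintf("(%.1f,%.1f]", seq(0, 0.9, 0.1), seq(0.1, 1, 0.1))
  structure(list(table = data.frame(subrange = labels, n_pairs = n_pairs,
                                    mean_shortest_path = mean_sp),
                 correlation = correlation),
            class = "similarity_distance_profile")
}

#' @export
print.similarity_distance_profile <- function(x, ...) {
  cat("<similarity_distance_profile> rank correlation:",
      if (is.na(x$correlation)) "undefined (degenerate)" else
        round(x$correlation, 3), "\n")
  print(x$table[x$table$n_pairs > 0, ], row.names = FALSE)
  invisible(x)
}
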