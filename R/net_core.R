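#' Ordered index over one kind of network node
#'
#' An `entity_index` fixes the identity and order of the drugs (or diseases)
#' for the lifetime of a run.  Every matrix type in the package carries one
#' (or two) of these, and cross-module operations fail loudly when indices
#' do not match, so rows and columns can never be silently permuted.
#'
#' @param ids character vector of unique identifiers; order is preserved.
#' @param kind `"drug"` or `"disease"`.
#' @return An object of class `entity_index` with fields `kind`, `ids`,
#'   `size`.
#' @export
entity_index <- function(ids, kind = c("drug", "disease")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (length(ids) < 1L) {
    stop("entity_index needs at least one id", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate ", kind, " ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(list(kind = kind, ids = ids, size = length(ids)),
            class = "entity_index")
}

#' @export
print.entity_index <- function(x, ...) {
  cat("<entity_index> ", x$size, " ", x$kind, "s: ",
      paste(utils::head(x$ids, 5L), collapse = ", "),
      if (x$size > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

same_index <- function(a, b) {
  inherits(a, "entity_index") && inherits(b, "entity_index") &&
    identical(a$kind, b$kind) && identical(a$ids, b$ids)
}

check_same_index <- function(a, b, what) {
  if (!same_index(a, b)) {
    stop("entity index mismatch in ", what,
         ": operands were built over different node sets", call. = FALSE)
  }
  invisible(TRUE)
}

check_binary <- function(values, what) {
  if (!all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)), arr.ind = TRUE)[1L, ]
    stop(what, ": non-binary value ", values[bad[1L], bad[2L]],
         " at row ", bad[1L], ", column ", bad[2L], call. = FALSE)
  }
  invisible(TRUE)
}

#' Binary entity-by-feature matrix
#'
#' Holds drug chemical fingerprints or disease symptom profiles as a dense
#' 0/1 matrix whose row order matches `index`.
#'
#' @param index an [entity_index()].
#' @param values numeric matrix with entries in `{0, 1}`; `nrow(values)`
#'   must equal `index$size`.
#' @return An object of class `feature_matrix` with fields `index`,
#'   `values`, `feature_count`.
#' @export
feature_matrix <- function(index, values) {
  stopifnot(inherits(index, "entity_index"))
  values <- as.matrix(values)
  if (nrow(values) != index$size) {
    stop("feature_matrix: ", nrow(values), " rows for ", index$size,
         " ", index$kind, "s", call. = FALSE)
  }
  check_binary(values, "feature_matrix")
  storage.mode(values) <- "double"
  rownames(values) <- index$ids
  structure(list(index = index, values = values,
                 feature_count = ncol(values)),
            class = "feature_matrix")
}

#' Binary drug-by-disease association matrix
#'
#' The bipartite network of known drug-disease associations, with drugs on
#' rows and diseases on columns everywhere in the package.
#'
#' @param drug_index,disease_index [entity_index()] objects of the two
#'   kinds.
#' @param values binary matrix, `n_r` x `n_d`.
#' @return An object of class `association_matrix`.
#' @export
association_matrix <- function(drug_index, disease_index, values) {
  stopifnot(inherits(drug_index, "entity_index"),
            inherits(disease_index, "entity_index"),
            drug_index$kind == "drug", disease_index$kind == "disease")
  values <- as.matrix(values)
  if (nrow(values) != drug_index$size || ncol(values) != disease_index$size) {
    stop("association_matrix: dimension mismatch with indices", call. = FALSE)
  }
  check_binary(values, "association_matrix")
  storage.mode(values) <- "double"
  dimnames(values) <- list(drug_index$ids, disease_index$ids)
  structure(list(drug_index = drug_index, disease_index = disease_index,
                 values = values),
            class = "association_matrix")
}

#' Symmetric nonnegative similarity matrix over one node kind
#'
#' @param index an [entity_index()].
#' @param values square numeric matrix, symmetric within `1e-9`,
#'   nonnegative; it is exactly symmetrized on construction.
#' @param stage pipeline stage label, one of `raw`, `adjusted`, `boosted`,
#'   `gip`, `composite`, `normalized`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(index, values,
                              stage = c("raw", "adjusted", "boosted",
                                        "gip", "composite", "normalized")) {
  stage <- match.arg(stage)
  stopifnot(inherits(index, "entity_index"))
  values <- as.matrix(values)
  if (nrow(values) != index$size || ncol(values) != index$size) {
    stop("similarity_matrix: not square over the index", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("similarity_matrix: non-finite entries", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-9) {
    stop("similarity_matrix: asymmetric beyond 1e-9", call. = FALSE)
  }
  if (min(values) < 0) {
    stop("similarity_matrix: negative entries", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(index$ids, index$ids)
  structure(list(index = index, values = values, stage = stage),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> stage=", x$stage, ", ", x$index$size, " ",
      x$index$kind, "s\n", sep = "")
  invisible(x)
}

#' Real drug-by-disease relevance score matrix
#'
#' @param drug_index,disease_index [entity_index()] objects.
#' @param values finite real matrix, `n_r` x `n_d`.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(drug_index, disease_index, values) {
  stopifnot(inherits(drug_index, "entity_index"),
            inherits(disease_index, "entity_index"))
  values <- as.matrix(values)
  if (nrow(values) != drug_index$size || ncol(values) != disease_index$size) {
    stop("score_matrix: dimension mismatch with indices", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("score_matrix: non-finite entries", call. = FALSE)
  }
  dimnames(values) <- list(drug_index$ids, disease_index$ids)
  structure(list(drug_index = drug_index, disease_index = disease_index,
                 values = values),
            class = "score_matrix")
}

#' Read a binary feature table from tab-delimited text
#'
#' Expects a header row, the first column holding entity identifiers and
#' the remaining columns binary feature values.  Row order in the file is
#' preserved in the resulting index.
#'
#' @param path file path.
#' @param kind `"drug"` or `"disease"`.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path, kind = c("drug", "disease")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) {
    stop("feature table ", path, " has no feature columns", call. = FALSE)
  }
  ids <- tab[[1L]]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = dimnames(raw)))
  if (any(is.na(values)) || !all(values %in% c(0, 1))) {
    bad <- which(is.na(values) | !(values %in% c(0, 1)), arr.ind = TRUE)[1L, ]
    stop("feature table ", path, ": non-binary cell '", raw[bad[1L], bad[2L]],
         "' at row ", bad[1L], " (id ", ids[bad[1L]], "), column ",
         colnames(raw)[bad[2L]], call. = FALSE)
  }
  feature_matrix(entity_index(ids, kind), values)
}

#' Write a feature table as tab-delimited text
#'
#' Inverse of [read_feature_table()]; writing then reading reproduces the
#' matrix bit-exactly.
#'
#' @param fm a [feature_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- data.frame(id = fm$index$ids, fm$values, check.names = FALSE)
  colnames(out) <- c("id", colnames(fm$values) %||%
                       paste0("f", seq_len(fm$feature_count)))
  utils::write.table(format(out, scientific = FALSE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a drug-disease association pair list
#'
#' Two-column tab-delimited text (drug id, disease id), no header.  Pairs
#' referencing identifiers absent from the supplied indices are rejected;
#' duplicated pairs are collapsed to a single association with a warning.
#'
#' @param path file path.
#' @param drugs,diseases [entity_index()] objects defining the id universe.
#' @return An [association_matrix()].
#' @export
read_associations <- function(path, drugs, diseases) {
  stopifnot(inherits(drugs, "entity_index"), inherits(diseases, "entity_index"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  values <- matrix(0, drugs$size, diseases$size)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("association list ", path, ": line ",
           which(lengths(parts) != 2L)[1L], " does not have 2 columns",
           call. = FALSE)
    }
    rid <- vapply(parts, `[[`, "", 1L)
    did <- vapply(parts, `[[`, "", 2L)
    i <- match(rid, drugs$ids)
    j <- match(did, diseases$ids)
    if (anyNA(i) || anyNA(j)) {
      bad <- which(is.na(i) | is.na(j))[1L]
      stop("association list ", path, ": unknown id in pair (",
           rid[bad], ", ", did[bad], ")", call. = FALSE)
    }
    if (anyDuplicated(cbind(i, j))) {
      warning("association list ", path,
              ": duplicated pairs collapsed to single associations",
              call. = FALSE)
    }
    values[cbind(i, j)] <- 1
  }
  association_matrix(drugs, diseases, values)
}

#' Write an association matrix as a two-column pair list
#'
#' @param am an [association_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(am, path) {
  stopifnot(inherits(am, "association_matrix"))
  idx <- which(am$values == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- paste(am$drug_index$ids[idx[, 1L]],
                 am$disease_index$ids[idx[, 2L]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write the top-k novel predictions to tab-delimited text
#'
#' Ranks the pairs that are unknown in `W` (entries with `W = 0`) by
#' descending score; ties are broken lexicographically by (drug id,
#' disease id) so output order is deterministic across runs.  Scores are
#' printed at 6 significant digits.
#'
#' @param F a [score_matrix()].
#' @param W an [association_matrix()] sharing both indices with `F`.
#' @param k number of pairs to write; truncated with a warning when fewer
#'   unknown pairs exist.
#' @param path output file path.
#' @return The written data frame, invisibly.
#' @export
write_ranked_predictions <- function(F, W, k, path) {
  stopifnot(inherits(F, "score_matrix"), inherits(W, "association_matrix"))
  check_same_index(F$drug_index, W$drug_index, "write_ranked_predictions")
  check_same_index(F$disease_index, W$disease_index, "write_ranked_predictions")
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  cand <- which(W$values == 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    warning("no unknown pairs to rank; writing empty prediction list",
            call. = FALSE)
    out <- data.frame(rank = integer(0), drug_id = character(0),
                      disease_id = character(0), score = character(0))
  } else {
    if (k > nrow(cand)) {
      warning("k = ", k, " exceeds the ", nrow(cand),
              " unknown pairs; truncating", call. = FALSE)
      k <- nrow(cand)
    }
    drug <- F$drug_index$ids[cand[, 1L]]
    dis <- F$disease_index$ids[cand[, 2L]]
    sc <- F$values[cand]
    ord <- order(-sc, drug, dis)[seq_len(k)]
    out <- data.frame(rank = seq_len(k), drug_id = drug[ord],
                      disease_id = dis[ord],
                      score = formatC(sc[ord], digits = 6, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
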