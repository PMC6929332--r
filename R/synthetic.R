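#' Configuration of the planted-block synthetic generator
#'
#' The generator emulates the three real inputs (drug fingerprints,
#' disease symptom profiles, known associations) with planted co-module
#' structure: drugs and diseases are partitioned into `n_blocks` blocks;
#' each block owns a binary feature template (density 0.3) from which
#' individual profiles deviate by independent bit flips, and associations
#' are drawn densely inside a block and sparsely across blocks — a direct
#' instantiation of the guilt-by-association premise.
#'
#' @param n_r,n_d number of drugs and diseases.
#' @param n_features_r,n_features_d feature counts (fingerprint and
#'   symptom analogues).
#' @param n_blocks number of planted co-modules.
#' @param within_assoc_prob,cross_assoc_prob association probabilities
#'   inside / across blocks; the planted signal requires
#'   `within > cross`.
#' @param feature_flip_prob per-bit deviation probability from the block
#'   template.
#' @param holdout_frac fraction of planted positives moved to the held-out
#'   truth matrix (absent from the observed matrix).
#' @param seed integer seed; the generator is a pure function of this
#'   config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_r = 60L, n_d = 50L,
                         n_features_r = 100L, n_features_d = 80L,
                         n_blocks = 5L,
                         within_assoc_prob = 0.3, cross_assoc_prob = 0.01,
                         feature_flip_prob = 0.05, holdout_frac = 0.2,
                         seed = 7L) {
  probs <- c(within_assoc_prob, cross_assoc_prob, feature_flip_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (within_assoc_prob <= cross_assoc_prob) {
    stop("within_assoc_prob must exceed cross_assoc_prob for a planted ",
         "signal", call. = FALSE)
  }
  if (holdout_frac <= 0 || holdout_frac >= 1) {
    stop("holdout_frac must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_r = as.integer(n_r), n_d = as.integer(n_d),
                 n_features_r = as.integer(n_features_r),
                 n_features_d = as.integer(n_features_d),
                 n_blocks = as.integer(n_blocks),
                 within_assoc_prob = within_assoc_prob,
                 cross_assoc_prob = cross_assoc_prob,
                 feature_flip_prob = feature_flip_prob,
                 holdout_frac = holdout_frac,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a planted-block heterogeneous network fixture
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_data`: `drug_features`,
#'   `disease_features` ([feature_matrix()]), `observed` and
#'   `held_out_truth` ([association_matrix()]; the truth matrix holds the
#'   planted positives withheld from `observed`), `drug_blocks`,
#'   `disease_blocks` (integer block labels), `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    rid <- sprintf("r%03d", seq_len(config$n_r))
    did <- sprintf("d%03d", seq_len(config$n_d))
    drug_index <- entity_index(rid, "drug")
    disease_index <- entity_index(did, "disease")
    drug_blocks <- rep_len(seq_len(config$n_blocks), config$n_r)
    disease_blocks <- rep_len(seq_len(config$n_blocks), config$n_d)

    make_features <- function(blocks, n_feat) {
      template <- matrix(stats::rbinom(config$n_blocks * n_feat, 1L, 0.3),
                         config$n_blocks, n_feat)
      prof <- template[blocks, , drop = FALSE]
      flips <- matrix(stats::rbinom(length(prof), 1L,
                                    config$feature_flip_prob),
                      nrow(prof), ncol(prof))
      (prof + flips) %% 2
    }
    Xr <- make_features(drug_blocks, config$n_features_r)
    Xd <- make_features(disease_blocks, config$n_features_d)

    draw_assoc <- function() {
      p <- ifelse(outer(drug_blocks, disease_blocks, `==`),
                  config$within_assoc_prob, config$cross_assoc_prob)
      matrix(stats::rbinom(length(p), 1L, as.vector(p)),
             config$n_r, config$n_d)
    }
    A <- draw_assoc()
    if (sum(A) == 0) A <- draw_assoc()
    if (sum(A) == 0) {
      stop("synthetic generator produced no associations twice; ",
           "raise the association probabilities", call. = FALSE)
    }
    pos <- which(A == 1)
    n_hold <- floor(config$holdout_frac * length(pos))
    held <- if (n_hold > 0L) sort(sample(pos, n_hold)) else integer(0)
    observed <- A
    observed[held] <- 0
    truth <- matrix(0, config$n_r, config$n_d)
    truth[held] <- 1

    structure(list(
      drug_features = feature_matrix(drug_index, Xr),
      disease_features = feature_matrix(disease_index, Xd),
      observed = association_matrix(drug_index, disease_index, observed),
      held_out_truth = association_matrix(drug_index, disease_index, truth),
      drug_blocks = drug_blocks, disease_blocks = disease_blocks,
      config = config), class = "synth_data")
  })
}

#' @export
print.synth_data <- function(x, ...) {
  cat("<synth_data> ", x$config$n_r, " drugs x ", x$config$n_d,
      " diseases, ", x$config$n_blocks, " blocks; ",
      sum(x$observed$values), " observed + ",
      sum(x$held_out_truth$values), " held-out associations (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}
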