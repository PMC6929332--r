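#' Pipeline configuration
#'
#' Collects every tunable of the prediction pipeline with its default.
#' Defaults follow the method's stated settings: restart weight
#' `alpha = 0.1`, logistic offset `d = log(999)` (so a similarity of 0 maps
#' to 0.001), 20 calibration shuffles, ClusterONE-style clustering with
#' per-node penalty 2, minimum cluster size 2 and overlap threshold 0.8,
#' and a Gaussian interaction profile bandwidth numerator of 1.
#'
#' One global `seed` fans out to stage-specific child seeds by fixed
#' offsets, so toggling one stage never perturbs another stage's
#' randomness.
#'
#' @param alpha walk weight in (0,1); `1 - alpha` is the restart mass
#'   returned to the known associations each step.
#' @param mode `"individual"` (per-node walk budgets from the bipartite
#'   Jaccard index) or `"fixed"` (one global budget per side, for
#'   ablations).
#' @param fixed_L_r,fixed_L_d integer walk lengths used only in fixed mode.
#' @param step2_enabled,step3_enabled,step4_enabled toggles for the
#'   logistic adjustment, cluster boost and GIP-kernel combination stages
#'   of the composite similarity (variants that drop exactly one stage).
#' @param logistic_d logistic offset `d > 0`.
#' @param x_star optional fixed informativeness threshold in (0,1]; when
#'   `NULL` it is calibrated from the data by [informative_threshold()].
#' @param shuffles number of calibration permutations.
#' @param clusterone_penalty,clusterone_min_size,clusterone_overlap
#'   clustering controls (see [cluster_one()]).
#' @param gip_gamma_tilde bandwidth numerator of the Gaussian interaction
#'   profile kernel.
#' @param neg_fraction fraction of unknown pairs used as negatives during
#'   cross-validation (1 = all unknown pairs).
#' @param seed integer master seed.
#' @return A list of class `ibrw_config`.
#' @export
ibrw_config <- function(alpha = 0.1,
                        mode = c("individual", "fixed"),
                        fixed_L_r = 2L,
                        fixed_L_d = 2L,
                        step2_enabled = TRUE,
                        step3_enabled = TRUE,
                        step4_enabled = TRUE,
                        logistic_d = log(999),
                        x_star = NULL,
                        shuffles = 20L,
                        clusterone_penalty = 2,
                        clusterone_min_size = 2L,
                        clusterone_overlap = 0.8,
                        gip_gamma_tilde = 1,
                        neg_fraction = 1,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  if (fixed_L_r < 0L || fixed_L_d < 0L) {
    stop("fixed walk lengths must be >= 0", call. = FALSE)
  }
  if (logistic_d <= 0) stop("logistic_d must be > 0", call. = FALSE)
  if (gip_gamma_tilde <= 0) stop("gip_gamma_tilde must be > 0", call. = FALSE)
  if (neg_fraction <= 0 || neg_fraction > 1) {
    stop("neg_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, mode = mode,
                 fixed_L_r = as.integer(fixed_L_r),
                 fixed_L_d = as.integer(fixed_L_d),
                 step2_enabled = isTRUE(step2_enabled),
                 step3_enabled = isTRUE(step3_enabled),
                 step4_enabled = isTRUE(step4_enabled),
                 logistic_d = logistic_d, x_star = x_star,
                 shuffles = as.integer(shuffles),
                 clusterone_penalty = clusterone_penalty,
                 clusterone_min_size = as.integer(clusterone_min_size),
                 clusterone_overlap = clusterone_overlap,
                 gip_gamma_tilde = gip_gamma_tilde,
                 neg_fraction = neg_fraction,
                 seed = as.integer(seed)),
            class = "ibrw_config")
}

# Fixed per-stage offsets from the master seed; kept < 2^31 for small seeds.
child_seed <- function(config, stage) {
  offsets <- c(threshold_drug = 101L, threshold_disease = 202L,
               cluster_drug = 303L, cluster_disease = 404L,
               folds = 505L, negatives = 606L, synthetic = 707L)
  config$seed + offsets[[stage]]
}
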