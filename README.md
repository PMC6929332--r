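# ibrw — individual-length bi-random walks for drug repositioning

`ibrw` ranks candidate drug–disease associations on a heterogeneous
network, for researchers doing computational drug repositioning: given
binary chemical fingerprints for drugs, binary symptom profiles for
diseases, and a list of known drug–disease associations, it scores every
unknown pair by how strongly the network topology supports the
guilt-by-association premise that similar drugs treat similar diseases.

## The method

Three networks are built and combined:

1. **Composite similarities** (separately for drugs and diseases), in four
   stages:
   - cosine similarity of the binary feature profiles,
     `S1(i,j) = <x_i, x_j> / (||x_i|| ||x_j||)`;
   - a shuffle-calibrated logistic adjustment
     `S2 = 1 / (1 + exp(-d/x* · S1 + d))` with `d = log(999)`, which
     shrinks similarities below the data-derived informativeness threshold
     `x*` towards 0.001 and enlarges those above it (midpoint 0.5 at
     `x*`);
   - a cluster boost: pairs co-occurring in a cluster of the
     association-sharing graph (edge weight = number of co-treated
     counterparts) are multiplied by `1 + f(C)`, where
     `f(C) = W_in / (W_in + W_bound + P(C))` is the cluster's
     cohesiveness;
   - averaging with a Gaussian interaction profile (GIP) kernel
     `exp(-γ ||IP_i - IP_j||²)`, `γ = γ̃ / mean(||IP||²)`.
2. **Per-node walk budgets.** A bipartite Jaccard influence index
   `JI(i,j) = |N_r(i) ∩ N̂_d(j)| / |N_r(i) ∪ N̂_d(j)|` (two-hop
   neighborhoods make the sets commensurate) is summed per row/column into
   individual walk lengths `L_r`, `L_d` — instead of one global walk
   length for all nodes.
3. **Gated bi-random walks with restart.** With `S̃` the Laplacian
   normalization `D^(-1/2) S D^(-1/2)` and `F⁰ = W`,

       F_r^t(i,·) = α F_r^(t-1)(i,·) S̃_d + (1-α) W(i,·)   while t ≤ ⌊L_r(i)⌋

   (frozen afterwards), mirrored on the disease side, and integrated as
   `F = (F_r + F_d)/2`.  Default restart weight `α = 0.1`.

A planted-block synthetic generator, 10-fold cross-validation with six
ranking metrics, and topology diagnostics (shortest-path margins,
similarity–distance profiles) are included, so the whole method is
testable without any external data.

## Worked example

```r
library(ibrw)

sim <- synth_generate(synth_config(seed = 7))   # 60 drugs x 50 diseases
sim
#> <synth_data> 60 drugs x 50 diseases, 5 blocks; 157 observed + 39 held-out
#>   associations (seed 7)

fit <- ibrw(sim$drug_features, sim$disease_features, sim$observed,
            ibrw_config(seed = 7))
fit
#> <ibrw_fit> 60 drugs x 50 diseases; mode=individual, alpha=0.1
#>   walk budgets: drugs max 7, diseases max 4

write_ranked_predictions(fit$scores, sim$observed, 5, "top5.tsv")
#>   rank drug_id disease_id     score
#> 1    1    r002       d037 0.0283604
#> 2    2    r060       d025 0.0267265
#> 3    3    r015       d025 0.0261746
#> 4    4    r006       d011 0.0260129
#> 5    5    r006       d001 0.0254052

cross_validate(sim$drug_features, sim$disease_features, sim$observed,
               ibrw_config(seed = 7), k = 10)
#> <metric_report> 10-fold cross-validation (seed 512)
#>     metric   mean     sd
#>      auroc 0.7875 0.0667
#>       aupr 0.0208 0.0052
#>   micro_f1 0.0562 0.0103
#>   macro_f1 0.5082 0.0123
#>  precision 0.0314 0.0060
#>     recall 0.4071 0.2333
```

The top predictions are unknown pairs whose drug and disease sit in the
same planted co-module (e.g. `r002`/`d037` both belong to block 2): the
walks concentrate score mass inside blocks, which is exactly the planted
ground truth.  The cross-validated AUROC of 0.79 sits close to the
Bayes-optimal ceiling of this generator (~0.85 — within a block, held-out
positives are statistically exchangeable with unknown pairs, so no method
can separate them); AUPR is low because all ~2850 unknown pairs serve as
negatives.  The fixed-length control `mode = "fixed", fixed_L_r = 0,
fixed_L_d = 0` collapses the scores to the training matrix and yields
AUROC 0.5 exactly.

## Command line

Every step is exposed as a subcommand of the installed launcher:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ibrw", package = "ibrw"))')
Rscript $CLI simulate --out sim --seed 7
Rscript $CLI predict  --drug-features sim/drug_features.tsv \
    --disease-features sim/disease_features.tsv \
    --associations sim/associations.tsv --out pred --seed 7 --top-k 10
Rscript $CLI evaluate --drug-features sim/drug_features.tsv \
    --disease-features sim/disease_features.tsv \
    --associations sim/associations.tsv --out eval --k 10 --seed 7
```

Also available: `similarity`, `walklen`, `diagnose`, `--config FILE`
(flat `key=value`, overridden by flags), `--show-config`.  Every run
writes a `manifest.json` with the config snapshot, seed, input digests and
package version.

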