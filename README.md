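# adrelabel

Cluster-based revision of Alzheimer's disease (AD) diagnostic labels on
heterogeneous clinical data, and a graph-neural-network classifier that
tests whether the revised labels are easier to learn.

## The problem

Clinical AD diagnosis does not always track the underlying biology:
biomarkers and cognitive symptoms correlate imperfectly, so a cohort's
CN / MCI / AD labels (cognitively normal, mild cognitive impairment,
Alzheimer's disease) contain cases whose measured pathology looks like a
different class. `adrelabel` implements a data-driven re-labelling
pipeline for baseline cohorts with sociodemographic, cognitive/functional
assessment (CFA) and regional tau-PET/MRI features:

1. **Preprocess** — similarity-matrix imputation for sociodemographic
   gaps, mean/mode imputation elsewhere, one-hot APoE4 encoding,
   non-negative shifting and min–max normalisation, so every feature lies
   in [0, 1].
2. **Embed and cluster** — UMAP (30 neighbours, minimum distance 0,
   5 dimensions) followed by k-means (k = 5), then rank features by
   information gain `IG(X) = H(cluster) − H(cluster | X)` against cluster
   membership and name clusters by their characteristics.
3. **Re-label** — the cluster with the highest proportion of clinician-
   diagnosed AD is the "AD cluster"; its CN and MCI members are
   re-labelled AD (never the reverse). Agreement with the original labels
   is quantified by unweighted Cohen's kappa
   `κ = (p_o − p_e)/(1 − p_e)`, and the re-labelled cases are validated
   post hoc against tau-sensitive regions and a CSF amyloid-beta
   biomarker held out from clustering.
4. **Classify** — an auto-metric graph neural network (AMGNN): edge
   weights are a trainable function of absolute differences in gender,
   age, education and family history; node representations combine the
   full feature vector with a support-label channel; training is episodic
   (meta-tasks of 64 nodes, cross-entropy on query nodes) and evaluation
   is one-shot (one labelled support per class). Paired experiments
   compare models trained on original vs re-labelled targets by macro
   one-vs-all AUC and balanced accuracy.

Because the cohort that motivated this design is access-controlled, the
package ships a first-class synthetic generator
(`generate_dataset()`) emulating its structure: 559 participants
(363/137/59 CN/MCI/AD), 224 features in three blocks, five latent
clusters (male-only, female-only, young-with-family-history, an AD-like
cluster with elevated tau regions, and an intermediate "catchall"),
~6% missingness, planted label noise inside the AD-like cluster, and an
amyloid-beta-like biomarker that decreases with severity.

## Worked example

The re-labelling arithmetic can be followed end to end from a cohort's
per-cluster diagnosis counts alone. With five clusters whose CN/MCI/AD
compositions are 6/18/26, 114/32/20, 96/28/7, 82/44/5 and 65/15/1:

```r
library(adrelabel)
comp <- data.frame(cn = c(6, 114, 96, 82, 65),
                   mci = c(18, 32, 28, 44, 15),
                   ad = c(26, 20, 7, 5, 1))
labels <- label_set(unlist(lapply(1:5, function(i)
  rep(c("CN", "MCI", "AD"), times = comp[i, ]))))
clusters <- cluster_assignment(rep(1:5, times = rowSums(comp)))

ad_cl <- identify_ad_cluster(clusters, labels)   # cluster 1: 26/50 = 52% AD
rel <- relabel_ad_cluster(labels, clusters, ad_cl)
sum(rel$relabel_mask)                            # 24  (6 CN + 18 MCI)
sum(rel$diagnosis == "AD")                       # 83  (59 + 24)
cohen_kappa(labels, rel)                         # 0.9170264
```

So 24 of 559 labels change, the AD class grows from 59 to 83, and the
revised labeling still agrees with the clinicians at κ ≈ 0.917 — a small,
targeted revision rather than a wholesale re-diagnosis. The 33 AD cases
outside the AD cluster are deliberately left untouched.

On the synthetic cohort the full pipeline runs in one call:

```r
res <- run_pipeline("results/run1", seed = 1, n_repeats = 10,
                    amgnn = amgnn_config(iterations = 100))
res$kappa          # agreement of the discovered re-labelling
res$report         # paired AUC / balanced accuracy, original vs re-labelled
```

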