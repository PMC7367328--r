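# hestage

Interpretable, feature-based staging of bladder tumor histology: telling
non-invasive papillary (**Ta**) from superficially invasive (**T1**) tumors on
hematoxylin-and-eosin (H&E) images. The two stages can look nearly identical
under the microscope, yet the distinction changes treatment; `hestage`
implements a fully automated pipeline that quantifies the three microscopic
patterns pathologists actually use and feeds them to transparent classifiers,
so every prediction can be traced back to named morphological features.

The pipeline:

1. **Synthetic phantoms** (`generate_phantom()`, `generate_dataset()`) —
   H&E-like tiles with pixel-level ground truth: pink eosin tissue, blue
   hematoxylin nucleus disks, thin white retraction cracks, large white
   inter-tissue gaps, illumination gradients/vignette, and sensor noise.
   Every downstream stage is testable against this ground truth.
2. **Preprocessing** (`crop_center_tiles()`, `flatfield_correct()`,
   `tissue_mask()`) — centered 700-px tiling, FFT-Gaussian flat-field
   illumination correction, white-threshold tissue masking.
3. **Pattern extractors** — *retraction artifact* (`segment_cracks()`:
   non-tissue components with equivalent diameter strictly above 40 px are
   inter-tissue space, the rest are peri-cellular cracks; 15 features),
   *pinker cytoplasm* (`eosin_features()`: pinkness index
   `p = (R − B)/255`, 13 features), and *desmoplastic reaction*
   (`segment_nuclei()`, `measure_nuclei()`, `desmo_features()`: nucleus
   morphometry, stromal texture and intensity; 675 features).
4. **Feature schema** (`merge_blocks()`, `clean_features()`,
   `subset_by_group()`) — a fixed 740-column raw export cleaned to 696
   analysis features in three overlapping groups (675/13/15; seven shared
   background features, 703 memberships).
5. **Ranking** (`rank_features()`) — 20 forests × 40 trees, every feature
   available at every split; per-feature mean Gini impurity decrease;
   `select_top_k()` picks the top 100.
6. **Classifiers** (`train_eval()`, `evaluate_models()`) — PNN (from-scratch
   Parzen-window Bayes classifier), SVM, logistic regression, AdaBoost
   stumps, random forest, MLP — evaluated by 20 repeats of
   balance-then-70/30-split, with accuracy at threshold 0.5, ROC curves,
   trapezoidal/Mann–Whitney AUC, and vertically averaged mean ROC bands.
7. **Unsupervised analysis** (`pca_features()`, `kmeans_sweep()`,
   `information_gain()`) — PCA by eigenvalue, k-means (k-means++, Lloyd)
   over k = 2..9, and the information gain of clusters about stage labels.

The model at the core of the classifier suite, the probabilistic neural
network, scores class *c* for a query *x* as

    g_c(x) = (1/n_c) Σ_i exp(−‖x − x_i‖² / 2σ²),   P(c|x) ∝ π_c g_c(x)

over standardized training vectors, with σ defaulting to 0.1 × the median
pairwise training distance.

## Worked example

```r
library(hestage)

ds  <- generate_dataset(12, 12, seed = 42)     # 12 Ta + 12 T1 phantoms
raw <- extract_feature_table(ds, flatfield = TRUE)
tbl <- clean_features(raw)                     # 24 rows x 696 features

rk <- rank_features(tbl, n_forests = 5, n_trees = 20, seed = 1)
head(tidy(rk), 5)
#>   feature                   importance  rank
#> 1 nuc_convex_area_mean          0.0413     1
#> 2 nuc_equiv_diameter_median     0.0387     2
#> 3 nuc_bbox_area_sd              0.0311     3
#> 4 stroma_hist_red_bin_32        0.0301     4
#> 5 nuc_equiv_diameter_q3         0.0296     5

ev <- train_eval(tbl, model = "PNN", features = select_top_k(rk, 30),
                 protocol = eval_protocol(repeats = 5, seed = 2))
glance(ev)
#>   model repeats mean_accuracy sd_accuracy mean_auc sd_auc
#> 1 PNN         5             1           0        1      0
```

Nucleus size and count statistics rank at the top — the desmoplastic pattern
carries the strongest signal, matching what pathologists report for real
slides. On these default-condition phantoms the classes are cleanly
separable, so accuracy and AUC reach 1 at this scale; the phantom generator
deliberately leaves the cytoplasm and retraction signals noisy and
overlapping (per-slide staining jitter, lognormal crack-area variation) so
the *relative* ordering of the three patterns is informative.

`autoplot()` methods draw the mean ROC band of a `train_eval()` result, the
top of a ranking, and PCA projections; `tidy()`/`glance()` return per-repeat
and one-row summaries.

A thin command-line front end lives at `inst/cli/stage.R`
(`simulate` / `extract` / `clean` / `rank` / `train` / `cluster` /
`pipeline`, each `--config`-driven), and `run_pipeline()` executes the whole
flow into a run directory with CSV outputs and a reproducibility manifest.

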