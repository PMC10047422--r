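---
title: "Unsupervised informative-frame selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised informative-frame selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frameclust)
```

## The problem and the modeling idea

Endoscopic (narrow-band imaging) video of the larynx yields a stream of
frames of which only a fraction is diagnostically informative; the rest are
blurred by motion, covered by specular reflections and saliva, or
underexposed. `frameclust` treats frame triage as a *clustering* problem
rather than a classification problem: frames are embedded as feature
vectors, projected to a low-dimensional space, and grouped by appearance.
Category names (blurred `B`, informative `I`, specular `S`, underexposed
`U`) enter only afterwards, when each cluster is assigned the category it
overlaps most — so the procedure needs reference labels only to *score*
itself, never to fit.

The fitting function `frameclust()` runs the cascade
embed → reduce → cluster → label → evaluate and returns a classed object;
each stage is also exported on its own. The assumptions are minimal but
real: frames of the same quality category must look more alike than frames
of different categories in the chosen embedding (a premise we test, see
below), and the number of categories must equal the number of clusters for
the bijective labeling to exist.

## Stages and the parameters that matter

**Embedding.** Two backends. `cnn-vgg16-random` resizes frames bilinearly
to 224×224, scales pixels to [0, 1] (no mean subtraction), and runs a
VGG16-architecture network with *random, untrained* weights (fan-in-scaled
Gaussian, fixed by `seed`), truncated after the first 4096-unit fully
connected activation. Which 4096-unit layer survives the truncation is a
genuine design choice — we keep the *first* fully connected activation and
record the choice in `backend_tag`. Random-projection features of this kind
preserve coarse appearance (exposure, contrast, texture energy), which is
what separates the four quality categories. `pixel-downsample` (32×32
grayscale, D = 1024) captures the same global appearance directly and runs
three orders of magnitude faster; the test suite uses it throughout.

**Reduction.** `pca` is implemented from the covariance eigenproblem
(column centering only, no variance scaling; a Gram-matrix route is used
when D > N; loadings carry a largest-element-positive sign convention so
results are reproducible across round-trips through text files). The
default retained dimensionality is d = 50, the scale at which CNN frame
embeddings typically keep ~80% of their variance. `tsne` and `umap` wrap
the established Rtsne and uwot implementations — their objectives are
standard and re-deriving them would add nothing — run single-threaded with
a fixed seed; both default to d = 2, the space in which the clustering and
validity analyses operate. UMAP defaults: `n_neighbors = 15`,
`min_dist = 0.1`.

**Clustering.** The four families share one contract (integer labels,
−1 reserved for density noise). Mini-batch *k*-means is implemented
in-package (k-means++ seeding, count-based per-center rates, best of
`n_init = 3` restarts by the full squared-error objective; with
`batch_size >= N`, the default below 1024 points, it reduces to Lloyd
behaviour). Agglomerative clustering delegates to `stats::hclust`
(Ward linkage by default). Spectral clustering builds a symmetrized
kNN (default) or RBF affinity, takes the unnormalized Laplacian
`L = D − W`, and runs k-means on the smallest-eigenvalue eigenvectors.
DBSCAN is the textbook algorithm; a point is core when at least `min_pts`
points (itself included) lie within `eps`. Euclidean distance everywhere.

**Labeling.** The greedy pass maps each cluster (ascending id) to its
argmax category, ties to the lowest category index in the fixed order
I, B, S, U. A greedy pass can map two clusters to one category, violating
the required bijection; we repair by exhaustively maximizing total
intersection over all K! bijections (24 candidates at K = 4) and flag the
result `mode = "optimal"` rather than failing silently. Since the row-wise
argmax upper-bounds every bijection, a bijective greedy result is provably
optimal — the exhaustive enumerator doubles as the test oracle. Noise
points are excluded from the mapping and counted as missed detections for
their true category downstream, never as true positives.

**Tuning.** Two cost functions drive hyperparameter search. For the
partition methods, `C = (1 − S_rec) + 0.1·|S_rec − S_pre|`, with S_rec and
S_pre the macro-averaged recall and precision after automatic labeling
(uniform class weights). For DBSCAN, whose cluster count is emergent,
`C = N_out + (1 − β)·(α·|N_in − K|) + β·σ` with defaults α = 100,
β = 0.01, K = 4. We read σ as the *mean squared deviation of per-cluster
sizes from the expected count* (180 at the reference dataset scale):
a population variance about a fixed reference, which is zero exactly when
every cluster hits the target — the reading consistent with the cost's
intent; the alternative (sample variance of the sizes) would vanish for
four equal clusters of any size. The search itself is either pure random
search or a small sequential model-based optimizer (Latin-hypercube
initialization, Gaussian-process surrogate with a squared-exponential
kernel on the unit cube, fixed length-scale 0.2, expected-improvement
acquisition over a random candidate set); budget defaults to 200
evaluations and the stop criterion is budget exhaustion. On the blob
benchmark both strategies reach the same (zero-cost) optimum, which is how
the BO-vs-random agreement is asserted in the tests.

**Evaluation.** One-vs-rest precision/recall/F1 with a return-0 convention
for zero denominators (this is what published comparison tables print for
degenerate clusterings). Summary rows use the *Tukey-hinge* IQR
(`stats::fivenum`): it is the quartile convention that reproduces the
published two-decimal IQR cells from their per-class values — with the
common length-4 rows, hinges are means of adjacent order statistics, and
no other standard quantile type matches all printed cells. ROC analysis
needs graded scores from a hard clustering: the score of a frame for
category g is the negative Euclidean distance to the centroid of the
cluster mapped to g, standardized per category — deterministic, monotone
in proximity, and the one construction we fix since the source of
published clustering ROC curves is not specified. The exact paired
Wilcoxon test drops zero differences, midranks ties, takes the smaller
signed-rank sum and enumerates all 2^n sign assignments
(p = 2·P(W ≤ w), capped at 1) — at n = 4 pairs an asymptotic test would
be meaningless. Cluster-number determination sweeps k = 2..6 with
k-means and picks the Calinski–Harabasz argmax, ties to the smallest k;
`WGSS = 0` yields `Inf` with a warning.

## The synthetic frame generator

`generate_frame_set()` emulates the four categories of a labeled NBI
laryngoscopy frame collection (180 frames per category at full scale,
pixel intensities 0–255). Every category has a machine-checkable
criterion, enforced by construction and asserted in tests:

* `I`: sharp curvilinear vessel texture at adequate exposure; bright
  specular disks covering at most 10% of the area (default 5%).
* `B`: the same texture family convolved with a wide Gaussian blur
  (default σ = 6 px at 128 px frames).
* `S`: bright bubbles/blobs — each independently white or light green —
  painted until they cover at least half the area (default 60%); "bright"
  means maximum channel ≥ 230.
* `U`: at least 90% of pixels below intensity 40 (default 95%), with a
  small regularly exposed portion allowed.

The intensity cutoffs (dark < 40, bright ≥ 230) are operational choices:
the categories are defined by area fractions, and fractions need
thresholds to be measurable. "Visible blood vessels" is qualitative; the
measurable proxy is a sharpness ordering — the Laplacian-response variance
of every `I` frame strictly exceeds that of the `B` frame generated from
the same seed.

Two generator features exist to make the *separability premise* hold in
the plain pixel embedding, and deserve explanation. First, categories
carry class-conditional illumination: informative frames sit in a bright,
tight exposure band (global mean pinned to 0.60–0.68), blurred frames in
a dimmer, compressed band (0.40–0.44, with contrast compressed by motion
integration) — emulating that blur episodes occur during repositioning
under poorer illumination. Without an exposure signature, a blurred frame
is statistically the *mean* of the sharp-texture family: the two classes
form concentric clouds whose within-class distance exceeds their
between-class distance, and no neighborhood-based method can separate
them at the 32×32 pixel level (a CNN embedding of real frames separates
them by texture statistics instead). Second, every frame receives a
smooth per-frame illumination-mottling field; this gives each class
isotropic multi-dimensional within-class variation, so classes form
round, unimodal clusters rather than one-dimensional strings that a
variance-ratio sweep would happily split. Both features are defaults of
the generator, fixed here once; tests at other settings only need the
stated pixel criteria.

What passing tests do and do not show: the synthetic frames share the
categories' measurable signatures (exposure, blur, specular coverage,
darkness) but none of the anatomy, patient-level correlation, video
redundancy, or annotation ambiguity of clinical material. Perfect recall
on synthetic frames demonstrates that the pipeline's machinery —
embedding, reduction, clustering, bijective labeling, scoring — is
correct and well-calibrated, not that clinical performance would be
perfect.

`generate_blob_embeddings()` is the second-tier generator: isotropic
Gaussian clusters with pairwise-equidistant centers (scaled coordinate
basis vectors, which is why it requires `dim >= n_clusters` at positive
separation), standing in for CNN embeddings when only the downstream
stages are under study.

## Numerical choices and degenerate inputs

* Reproducibility: every randomized stage draws a sub-seed derived
  deterministically from the master seed and the stage name; UMAP runs
  with `n_threads = 1, n_sgd_threads = 0`; refitting reproduces objects
  bit-for-bit, and the pipeline's JSON artifacts are byte-identical
  across re-runs.
* PCA errors on zero-variance input and on d outside [1, min(N−1, D)];
  explained-variance ratios are non-increasing and sum to ≤ 1.
* Metrics return 0 on zero denominators; Calinski–Harabasz returns `Inf`
  with a warning when WGSS = 0; silhouette assigns 0 to singleton
  clusters and errors on a single cluster; the Wilcoxon test returns
  p = 1 with a flag when all differences are zero.
* Mini-batch k-means reseats empty clusters on the farthest points and
  keeps the best of several restarts, which is what makes its
  squared-error objective non-increasing in k in practice.
* The exhaustive label-map enumerator is limited to K ≤ 10 (10! ≈ 3.6M
  bijections); the pipeline's K is 4.

## Problem sizes used in the shipped studies

The test suite and acceptance studies run at deliberately moderate scale,
chosen as the smallest sizes at which the studied effects are stable:
frame sets of 45–60 frames per category at 128 px for the end-to-end and
cluster-number studies (the full reference scale is 180 per category at
1920×1072; the pipeline is size-agnostic), 10 independent seeds for the
stochastic cluster-number criterion, and blob benchmarks of 120–720
points. The CNN backend is exercised on a handful of frames — enough to
pin down its dimensionality, determinism and separability — while the
pixel backend carries the bulk of the studies.

## Known limitations

* The bijective labeling requires exactly as many clusters as categories;
  many-to-one label transfer (K ≠ G) is out of scope.
* Out-of-sample `predict()` is available only for the `none` and `pca`
  reductions; t-SNE and UMAP fits are transductive here.
* The BO surrogate uses a fixed kernel length-scale rather than marginal
  likelihood optimization — adequate for the low-dimensional spaces it
  searches, not a general-purpose optimizer.
* Synthetic frames model category signatures, not laryngeal anatomy; see
  above for what that implies about external validity.
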