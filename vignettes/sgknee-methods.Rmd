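---
title: "Methods: multi-view knee MRI classification in sgknee"
author: "sgknee authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view knee MRI classification in sgknee}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sgknee)
```

## The problem

Radiologists diagnose anterior cruciate ligament (ACL) tears on knee MRI by
integrating evidence across many slices and several acquisition planes:
fiber discontinuity, contour change and signal abnormality may each be
visible in only a few slices of one view.  `sgknee` models this reading
process: a per-slice convolutional backbone, an attention module that
couples neighbouring slices, and a decision-level fusion of the three
views.  Torn exams are the positive class throughout; sensitivity is recall
on tears, specificity recall on intact knees.

## Data model

A volume is one view's slice stack, an `L × H × W` array (`ExamVolume`);
the reference dialect is `L × 256 × 256` with `L` varying per exam and per
view.  Volumes are stored one-per-exam-view in NumPy `.npy` containers
(C-order), so datasets interoperate with Python tooling; any numeric dtype
is promoted to double on read.  A `DatasetManifest` is an ordered CSV of
`exam_id, label, axial, coronal, sagittal`.

## Dual-scale data augmentation

Training batches pass through, per view:

1. random crop, one shared window per volume (default 256 → 224);
2. normalization `(p − m)/sd` with a single `(m, sd)` pair computed on the
   pooled training split (not per view, not per volume), frozen thereafter;
3. at most one of *erasing* or *mixup*, at one of two scales.

At the **spatial scale**, each touched slice (a `layerRatio` fraction of
the stack inside the training pipeline; the standalone operations default
to all slices) receives a square block with side `round(side × ratio)`
placed uniformly among fully-inside positions;
erasing zeroes it, mixup replaces it by `λ·self + (1−λ)·donor` where the
donor block comes from a uniformly chosen *other slice of the same view* at
an independent position.  At the **layer scale**, `round(L × ratio)` whole
slices are erased, or mixed with slices drawn from the *other views*
(nearest-neighbour resized if needed).  Mixing weights are
`λ ~ Beta(α, α)`.  Class labels are never modified; augmentation perturbs
intensities only.

Interpretation choices made here, configurable where noted:

* *Block-size convention.*  "Size `input × ratio`" is read as the block
  **side**, so the erased area fraction is `ratio²` (ratio 0.5 clears 25%
  of the pixels, ratio 0.75 still leaves over 40% intact — consistent with
  over-augmentation degrading, rather than destroying, the input).  An
  `area` mode making the ratio the erased area fraction is available
  (`blockMode` in `augmentConfig()`).
* *Mixing distribution.*  The Beta shape is unconstrained by the protocol
  we follow; we default to the common mixup choice `α = 0.4`.
* *Per-sample op choice.*  Erase vs mixup vs none, and spatial vs layer
  scale, are drawn per exam with probabilities `pErase = pMixup = 0.5`,
  `pLayerScale = 0.5`; the two ops and the two scales are mutually
  exclusive per sample so their combined strength stays moderate.
* Default ratios follow the ablation-selected values: erasing 0.5, mixup
  0.25, layer ratio 0.25.

Each stage draws from a named substream of the run seed
(`withSubstream()`), so toggling one stage never shifts another's draws.

## Backbone and head

`small_cnn` (the desk-scale default) is three convolution blocks with ReLU
(5×5 stride 2, then two 3×3), the first two followed by 3×3/2 max pooling,
ending at `C` channels.  The max pooling is load-bearing: the phantom's
tear cue is a few bright voxels, and peak-preserving downsampling keeps it
salient through the head's spatial average pooling, where a purely strided
stack leaves a signal so diluted that optimization becomes
initialization-dependent.  `mrnet_alexnet_like` recreates
the classic 11/5/3/3/3 AlexNet feature geometry (256 channels, max
pooling) with random initialization — no pretrained weights are shipped.
Slices share the backbone; outputs stack
into `B × L × C × H × W`.  The head average-pools each slice, takes the
element-wise **max over slices** (a finding visible anywhere in the stack
drives the score, and variable `L` is handled naturally), and applies one
fully connected layer with a 2-class softmax.

## Selective group attention

For a layer-group size `n`, the feature map is folded so that blocks of `n`
consecutive slices become channel groups: `L/n × (C·n) × H × W` (channel
index `c + C(j−1)` for slice `j` of the block).  If `n` does not divide
`L`, the final slice is repeated (edge replication) and the padding is
dropped on unfolding, so the module preserves shape for every `L`.

Within each group:

* 1-D average pools over width and height give directional descriptors;
  their concatenation passes through a **shared 1×1 convolution** (one
  weight matrix per branch, shared across groups), is split back into the
  two directions and sigmoid-activated, and the rank-1 outer product forms
  the positional map `A'[h, w] = A'_H[h]·A'_W[w]` per channel.
* a **global branch** — depthwise 3×3 convolution then global average
  pool — yields one scalar `g` per group-channel.
* the gate is `M = σ(A' ⊙ g)` and the group output is the element-wise
  product `C_n ⊙ M`.  Fusing the positional map with the global scalar
  multiplicatively inside one sigmoid is the simplest contract that lets
  the global context sharpen or flatten the positional attention; it is
  isolated in one function so alternatives are swappable.

The selective stage runs `K` such branches with different `n` (default
`{1, 2, 4}`), sums them, pools the sum over layers *and* space to a
length-`C` descriptor (pooling over layers keeps branches with different
`L/n` comparable), squeezes it through a bottleneck FC (reduction `r = 4`,
minimum width 8), and applies `K` parallel FCs with a softmax **across
branches** per channel.  The output is the weighted branch sum
`Σ_k z_k ⊙ F_k` — the selective-kernel convention: the gate selects among
the candidate crop-group scales rather than rescaling the pooled
descriptor, which would discard the branch maps entirely.  Each view trains
its own SG weights.

## Loss and optimization

With `p` the predicted tear probability, `p_t = p` for torn and `1 − p` for
intact exams, and `α_t = α` resp. `1 − α`:

* weighted loss `−α_t log p_t`;
* focal loss `−α_t (1 − p_t)^γ log p_t`;
* training loss = their sum.

`α` defaults to one minus the training-split prevalence so the rarer torn
class is up-weighted; `γ` defaults to the canonical focal value 2 (`γ = 0`
recovers the weighted loss exactly, which the tests assert).  `log` is
clamped at `1e-12`.  Optimization is Adam (lr `1e-5`, weight decay 0.01)
with the learning rate multiplied by 0.8 when the tune loss fails to
improve for 5 epochs; batches collate volumes to the batch-median `L` by
edge replication.  The decision threshold is 0.5 on the tear probability;
AUC is threshold-free (midrank Mann–Whitney, exact under ties).

Gradients come from a small reverse-mode tape over R arrays with
Rcpp/Armadillo convolution kernels; every analytic gradient is verified
against central finite differences in the test suite (worst relative error
around `1e-10`).

## Fuzzy-distance fusion

Per class `j`, the three views' confidences are compared with the ideal
vector `(1, 1, 1)`: Euclidean and Manhattan norms of
`P_j = 1 − (S_aj, S_cj, S_sj)` and the cosine distance
`1 − cos(S_j, 1)`, multiplied into `I_j`; prediction is `argmin_j I_j`.
Conventions fixed here: cosine distance is `1 −` cosine similarity (an
all-zero score triple gets the maximal distance 1); argmin ties break to
the lowest class index (so exactly symmetric scores yield "intact", the
safer default for a ranking rule); with a single view the cosine term
degenerates and the rule collapses, so single-view mode falls back to the
view's own argmax.  For ROC analysis a fused continuous score
`I₀/(I₀+I₁)` is emitted — a package convention (distances are
smaller-is-better), used only for threshold-free evaluation, never for the
decision.

## The synthetic phantom

`generateExam()` renders one latent 3-D scene per exam: an ellipsoidal
joint background (intensity 0.3) crossed by a bright diagonal band
(intensity 1.0, width 5 voxels) with jittered endpoints.  A torn exam
interrupts the band with a 10-voxel gap — the gap interior reverts to the
background — and adds a small hyperintense blob (intensity 1.25) displaced
perpendicular to the band, a geometric stand-in for fiber discontinuity
plus signal abnormality.  The three views are axis-permuted,
slice-subsampled renderings of the same scene with independent Gaussian
noise (SD 0.05), so they are correlated but not identical; per-view slice
counts are drawn from 16–24.  Default prevalence is 18.4%, matching a
typical clinical training cohort.

What the phantom does **not** emulate: MR physics and acquisition
artefacts, anatomical variability, partial tears, reader disagreement, or
any realistic texture.  Passing the end-to-end tests therefore shows that
the implementation can learn a slice-localized, multi-view-consistent
lesion signature under class imbalance — not that the model reaches any
particular clinical accuracy.

The analytic band mask (`bandMask()`) gives a sufficient statistic for the
label; a logistic model on the band-mean intensity must reach AUC > 0.95
on 200 exams, which the tests assert as the floor below which downstream
learning checks would be meaningless.

## The desk-scale study

`runPhantomStudy()` is the package's end-to-end experiment and the basis of
the acceptance script: 400 exams at spatial size 64, one stratified fold
(256 train / 64 tune / 80 validation), 15 epochs, batch 8, a 16-channel
`small_cnn`, crops 64 → 56, and learning rate `5e-3` — the protocol default
of `1e-5` is sized for a far larger backbone and dataset, and a small CNN
trained for 15 epochs needs a correspondingly larger step.  These sizes
were chosen once as a realistic single-core workload (roughly a quarter
hour).
Baseline (backbone only) and full (DDA + SG) models are trained per view
with a shared seed; the comparison uses the mean validation AUC across the
three views, which is steadier than any single view at `n = 80`.  The
expected qualitative ordering is full ≥ baseline, full mean AUC ≥ 0.85, and
fused accuracy within 0.02 of the best single view.

## Known limitations

* The tape is minimal by design: no GPU, no graph reuse, double precision
  only.  Training beyond desk scale is out of scope.
* The cosine component of fusion is scale-invariant, so a class whose
  scores vary more across views is penalized even at equal means; with
  strongly disagreeing views the product rule can be dominated by that
  term.
* The AlexNet-like backbone reproduces the topology, not any pretrained
  representation; its clinical-scale behaviour is untested here.
* Reported-metric consistency checks validate arithmetic coherence of
  published summaries; they are not a reproduction of clinical results,
  which would require the original datasets and GPU-scale training.
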