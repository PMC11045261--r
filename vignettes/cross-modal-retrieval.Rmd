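---
title: "Cross-modal rice leaf disease retrieval: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal rice leaf disease retrieval: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Rice leaves affected by bacterial leaf blight, blast, brown spot or tungro
can be described either by a photograph or by an expert caption ("brownspot
leaf large three dark spots lower"). Cross-modal retrieval asks for the
caption best matching a query image and vice versa. `cmrice` implements a
dual-encoder visual-semantic embedding pipeline for this task:

1. **Encoders.** Each image is dissected into patches and each caption into
   word tokens; both fine-grained sequences are projected into a shared
   d-dimensional space. Global embeddings are arithmetic means over the
   sequence axis, $\bar v = \frac1m \sum_i v_i$ and
   $\bar w = \frac1l \sum_j w_j$, then unit-normalized so that dot products
   equal cosine similarities.
2. **TMS enhancement.** Before pooling, a two-way mixed self-attention layer
   re-weights the sequence: two learnable logit arrays (forward and
   backward) are pushed through softmaxes along several axes, summed, and
   applied as attention; the two attended sequences are mixed with fixed
   coefficients $0.6$ (forward) and $0.4$ (backward).
3. **FNE-HNM triplet objective.** Training minimizes
   $\mathcal L = \alpha\,\mathcal L_{HNM} + (1-\alpha)\,\mathcal L_{FNE}$,
   where each component is the symmetric two-hinge triplet loss
   $[m - s(\bar v,\bar w) + s(\bar v,\bar w^-)]_+ +
    [m - s(\bar v,\bar w) + s(\bar v^-,\bar w)]_+$
   with margin $m = 0.2$. The HNM negatives are the hardest in the batch
   (row/column maxima of the masked cost matrices); the FNE negatives are
   drawn from a momentum memory bank with weights that demote suspected
   false negatives.
4. **False-negative posterior.** Matched and unmatched similarity sets are
   modeled as Gaussians whose running means and standard deviations are
   accumulated over the epoch. The probability that a labeled negative with
   similarity $s$ actually matches its anchor is the Bayes posterior
   $P(c\,|\,s) = \frac{p\,f_+(s)}{p\,f_+(s) + (1-p)\,f_-(s)}$ with a small
   Bernoulli prior $p$ (default $10^{-4}$). Sampling weights are
   $e^{-P(c|s)}$ for ordinary negatives and $e^{-a\,(s_- - s_+)^2}$
   (density $a = 0.5$) for easy negatives whose posterior is at or below
   $\lambda = 0.01$.
5. **WBA schedule.** The learning rate ramps linearly for the first 1/20 of
   the optimizer steps up to the initial rate, then decays multiplicatively
   by a loudness factor
   $\ell_{\min} + (\ell_{\max}-\ell_{\min}) e^{-r\,t/T}$, floored at a
   minimum rate.
6. **Evaluation.** Galleries are ranked by cosine similarity;
   $R@K = TP/(TP+FN)$ is reported for $K \in \{1, 5, 10\}$ in both
   directions. None of the negative-sampling machinery runs at inference.

The pretrained vision/text transformer backbones used at full scale are
deliberately pluggable and not bundled; the package ships tiny
deterministic encoders so that every loss, sampler, scheduler and
evaluation component can be verified end to end on one CPU in seconds.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `margin` | 0.2 | triplet ranking margin (cosine units) |
| `alpha` | 0.5 | weight of the HNM loss in the total objective |
| `prior_p` | 1e-4 | Bernoulli prior of a negative being a false negative |
| `density_a` | 0.5 | easy-negative sampling density |
| `easy_threshold_lambda` | 0.01 | posterior cutoff of the easy branch |
| `min_stats_count` | 256 | observations per similarity set before the Gaussian model is trusted |
| `capacity` | 8192 | memory bank entries per modality |
| `momentum` | 0.995 | momentum-encoder coefficient |
| `initial_learning_rate` | 4e-5 | peak rate after warm-up (full-scale transformer fine-tuning value) |
| `batch_size`, `epochs` | 32, 110 | full-scale training defaults |
| `dim` | 256 | shared embedding dimension of the tiny backend |

`alpha` is not pinned down by the method description, so the symmetric 0.5
is the default and it is exposed in `loss_config()`. The prior, density and
threshold defaults are the values reported to work best on held-out
validation data at full scale.

# Design decisions in detail

## TMS weight normalization

The forward branch sums three softmax applications of the same logit array
(along the column, row and head axes) and the backward branch sums two.
The individual terms are each a probability distribution **along their own
axis**, but their sum is not a probability distribution along any axis, and
a plain division by the number of terms does not fix this (only the
column-axis softmax is row-stochastic; the row- and head-axis terms are
not). Since the attended features should be convex combinations of the
input positions — this is what keeps feature magnitudes stable and what
makes "the weights form valid probability distributions" true of the
operator actually applied — the default convention renormalizes each row of
the summed weights (`normalization = "row"`). Two fidelity variants are
kept: `"mean"` divides by the number of terms, `"none"` applies the raw
sums. Under `"row"`, zero-initialized logits give exactly uniform
attention, every output coordinate lies inside the convex hull of the
corresponding input coordinate, and the layer at initialization maps every
position to the sequence mean — so it leaves mean pooling untouched until
training moves it.

The backward branch carries its own logit parameters even though the
printed formula reuses the forward array; the surrounding text names two
parameter sets, and a backward branch that merely recombined the forward
logits could not attend differently.

Heads are averaged after attending. The head count is configurable
(default 1); the algorithm sets a head count but never specifies how heads
recombine, and averaging is the simplest contract consistent with the
shapes.

## The two HNM loss variants

The six-step workflow ends with
`cost_s.sum + cost_im.sum - hard_neg_s.sum - hard_neg_im.sum`, which
*subtracts* the hardest-negative terms — the opposite of the stated goal of
concentrating on the hardest negatives, and a quantity that collapses to
exactly zero for batch size 2 (each row/column has a single off-diagonal
entry, so the sum equals the maximum). Both readings are implemented:
`hnm_variant = "as_printed"` (default, faithful to the workflow) and
`"conventional"` (the VSE++-style `hard_neg_s.sum + hard_neg_im.sum`). The
training loop does not depend on the choice: it builds its HNM hinge from
the per-anchor hardest negatives directly, which both variants agree on.

## The easy-negative threshold

The printed sampling rule gates the easy branch on
"$P \le \lambda^2$" while the accompanying sentence configures
$\lambda = 0.01$ as the threshold. The default reads the gate as
$P \le \lambda$; `sampler_config(square_lambda = TRUE)` switches to the
literal $\lambda^2$.

## Similarity statistics

The matched set $S^+$ only receives a batch diagonal entry when it strictly
exceeds every off-diagonal entry of its row — early in training, matched
scores that lose to negatives are unreliable draws from the matched
distribution. $S^-$ is unfiltered, as written. The accumulator is Welford's
online algorithm applied value by value in a fixed order, so results are
independent of batching to machine precision. Statistics reset at each
epoch boundary: the embedding space drifts during training and an
epoch-sized window tracks it while staying deterministic. Before both sets
hold `min_stats_count` observations the sampler returns uniform weights
(pure hard-negative behavior); there is no principled cold-start posterior.
The Gaussian densities floor sigma at $10^{-6}$ so a degenerate batch
cannot collapse the model, and sampling weights are floored at $10^{-12}$:
$e^{-x}$ never reaches zero analytically, the floor only guards numeric
underflow.

## Memory bank and candidate pool

The bank is a strict FIFO queue per modality filled with momentum-encoder
embeddings, which carry no gradients. The batch's momentum embeddings are
enqueued *before* negatives are sampled, so the candidate pool is always
exactly the bank contents — the current batch participates through its
momentum copies, and with a warm bank the pool size is the capacity
regardless of batch size, which is what makes retrieval training robust to
small batches. Batch-local hardest negatives do receive gradients
(standard margin-loss behavior); bank negatives are constants.

## The WBA schedule

Iterations are optimizer steps, not epochs; `max_iterations` is computed at
startup as epochs times steps per epoch. Loudness is recomputed from its
closed form at every step (the alternative — recomputing only when a new
solution is accepted — is under-specified). The loudness band and pulse
rate (0.95, 1.0, 0.9) are unstated at full scale; the defaults give a
gentle geometric decay that approaches the floor over a 110-epoch run at
batch 32. The metaheuristic "generate a new solution" phase is an optional
exploration mode (seeded multiplicative rate perturbations, accepted only
on validation improvement) and is off by default; the deterministic
composite of warm-up and loudness decay is the schedule proper. The
warm-up length `floor(max_iterations / 20)` is clamped below at 1 so tiny
runs never divide by zero.

## Tiny encoders and feature standardization

The tiny image backend summarizes each patch by per-channel means and
standard deviations placed in patch-specific coordinate blocks, so mean
pooling preserves the spatial layout; the text backend hashes whitespace
tokens into a fixed 64-slot vocabulary. Both raw representations are
standardized per coordinate (mean/sd over the training split) before the
trainable projection: the shared baseline — leaf color filling most of
every image, constant template tokens in every caption — otherwise
dominates the raw features, making all embeddings of a class nearly
parallel and stalling cosine-margin training. The projections are seeded
random linear maps at initialization, so the whole encoder is a pure
function of (input, seed).

Captions are padded (or truncated) to a fixed token capacity with all-zero
rows so one TMS parameter set serves the whole batch; the rendered worlds
use fixed-length seven-token templates, so padding is inert there.

The training optimizer is plain SGD at the WBA-scheduled rate. For the
desk-scale worlds the experiment configuration uses an initial rate of 0.3:
hinge losses on unit-sphere embeddings with linear encoders tolerate and
need much larger steps than transformer fine-tuning, whose 4e-5 remains the
package default. Backpropagation through projection, TMS, pooling and
normalization is analytic and is verified against finite differences in
the test suite.

# The synthetic worlds

Two generators exist, separating math verification from representation
learning.

**Embedding worlds** (`generate_embedding_world`) produce paired unit
embeddings directly in the shared space. Every image shares a common
component of weight $\sqrt\lambda$ with $\lambda = \mu_-/\mu_+$, so
unmatched cosines average $\mu_-$ exactly; each caption is constructed from
its image with a cosine drawn from $N(\mu_+, \sigma_+)$, so matched
cosines follow the matched distribution exactly. The default dimension 32
sets the unmatched spread near $\sigma_- = 0.15$ (the spread, unlike the
mean, is governed by the dimension). Planted false negatives rebuild a
caption to satisfy matched-distribution cosines with *both* its own image
and the most similar other image of its class — the nearest neighbour is
the semantically natural duplicate partner, and choosing it keeps the
two-cosine constraint feasible on the sphere, so the planted similarity
draws are untruncated and a location test cannot tell planted negatives
from genuine positives. That indistinguishability is precisely what makes
them a fair probe of the false-negative posterior.

**Rendered worlds** (`render_image_caption_world`) write PNG leaf images
and a TSV caption table in the layout `load_pairs` reads. Class determines
the leaf color; lesion count (one-four), size (small/large), shade
(dark/pale) and location (upper/lower/left/right) are drawn per image and
named verbatim in a fixed seven-token caption. The small attribute
vocabulary is deliberate: attribute collisions yield naturally occurring
false-negative captions, mirroring how equivalent descriptions of two
same-disease leaves arise in real annotation.

What the generators do **not** emulate: photographic texture, background
clutter, annotation noise, vocabulary variation between annotators, or
one-to-many image-caption relations. Passing desk-scale tests therefore
shows the machinery is implemented correctly and that the learning signal
flows end to end; it does not certify full-scale accuracy on field data,
which additionally depends on the pretrained backbones.

# Problem sizes used by the verification suite

The test suite exercises the components at sizes chosen to keep a full run
in well under a minute of compute while leaving no branch untested: loss
oracles at batch sizes 2/3/5, posterior recovery on a 1,000-pair world with
1,000 scored negatives (about 5% planted), and end-to-end training on a
rendered world of 4 classes x 50 pairs (8:1:1 split, 30 epochs, batch 32,
dimension 256) — a 20-item test gallery where chance R@1 is 0.05 and the
trained model reaches 0.5-0.7 in both directions, comfortably beyond the
five-times-chance requirement, with bitwise-identical replays under a fixed
seed.

# Known limitations

* Real mode (pretrained transformer backbones) is a configuration slot; no
  weights ship with the package and no fine-tuning recipe is provided.
* The Gaussian similarity model is taken as given; no kernel-density or
  skewed alternatives.
* Ground truth at evaluation is strictly one-to-one; multi-positive
  galleries are out of scope, so naturally duplicated captions in a test
  gallery bound R@1 below 1 by construction.
* The exploration mode of the scheduler is an extrapolation beyond the
  deterministic schedule and is off by default.
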