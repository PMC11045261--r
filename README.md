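# cmrice — cross-modal image–text retrieval for rice leaf disease

`cmrice` is an R toolkit for dual-encoder cross-modal retrieval of rice
leaf diseases: given a leaf photograph, find the expert caption that
describes it, and given a caption, find the leaf image it describes. It is
aimed at researchers in plant phenotyping and agricultural informatics who
want the full training-and-evaluation machinery of a modern
visual-semantic-embedding retrieval framework in a form that is verifiable
on a single CPU, without GPUs, pretrained transformer weights, or access to
a field-collected dataset.

## What it implements

* **Dual encoders with mean pooling.** Patch and word feature sequences are
  projected into a shared d-dimensional space; global embeddings are
  sequence means, `v̄ = (1/m) Σ vᵢ`, `w̄ = (1/l) Σ wⱼ`, unit-normalized so
  dot products are cosine similarities `s(v̄, w̄)`. Tiny deterministic
  backends (patch statistics; hashed tokens) stand in for the pluggable
  pretrained backbones.
* **TMS** — two-way mixed self-attention feature enhancement: learnable
  forward/backward attention logit arrays, softmaxed along several axes,
  applied to the sequence and mixed with fixed coefficients
  `0.6 · forward + 0.4 · backward`.
* **FNE-HNM triplet objective.** The symmetric hinge loss
  `[m − s(v̄,w̄) + s(v̄,w̄⁻)]₊ + [m − s(v̄,w̄) + s(v̄⁻,w̄)]₊` (margin
  `m = 0.2`) evaluated with two kinds of negatives and mixed as
  `α·L_HNM + (1−α)·L_FNE`: batch-hardest negatives (HNM, the row/column
  maxima of the masked cost matrices of the batch score matrix `im @ sᵀ`)
  and false-negative-aware sampled negatives (FNE). A negative with
  similarity `s` is a suspected false negative with Bayes posterior
  `P(c|s) = p·f₊(s) / (p·f₊(s) + (1−p)·f₋(s))`, where `f₊`, `f₋` are
  Gaussian models of the matched/unmatched similarity sets accumulated
  online during training, and `p` is a small prior (default 1/10,000);
  sampling weights are `exp(−P(c|s))`, or `exp(−a·(s₋−s₊)²)` for easy
  negatives with posterior ≤ 0.01.
* **Momentum memory bank** — a fixed-capacity FIFO queue (default 8,192
  entries per modality) of momentum-encoder embeddings that serves as the
  negative candidate pool, making training robust to small batch sizes.
* **WBA learning-rate schedule** — linear warm-up over the first 1/20 of
  optimizer steps up to the initial rate (default 0.00004), then
  multiplicative decay by a loudness factor
  `ℓ_min + (ℓ_max − ℓ_min)·exp(−r·t/T)` floored at a minimum rate.
* **Recall@K evaluation** — cosine-ranked galleries, `R@K = TP/(TP+FN)`
  for K ∈ {1, 5, 10}, both retrieval directions.
* **Synthetic worlds** — seeded generators of (a) paired embeddings with
  exact matched/unmatched similarity distributions and *planted false
  negatives*, and (b) rendered PNG leaf images with attribute-bearing
  captions, so every component above is testable without external data.

## Worked example

Train on a rendered synthetic world (4 disease classes × 50 image–caption
pairs, 8:1:1 split) for 30 epochs and evaluate on the held-out test
gallery:

```r
library(cmrice)

cfg <- experiment_config(
  world = world_config(n_classes = 4, n_per_class = 50, seed = 7),
  epochs = 30, batch_size = 32, dim = 256,
  initial_learning_rate = 0.3, min_learning_rate = 3e-4, seed = 7)

fit <- train_retrieval(cfg)
evaluate_retrieval(fit)
#> Bidirectional retrieval over a gallery of 20 pairs
#>   image_to_text R@1=0.550  R@5=1.000  R@10=1.000
#>   text_to_image R@1=0.650  R@5=0.950  R@10=1.000
```

Chance-level R@1 on a 20-item gallery is 0.05, so the trained tiny
encoders retrieve the correct caption first for 55% of image queries (and
the correct image for 65% of caption queries) — an eleven-to-thirteen-fold
improvement over chance, with the correct answer almost always in the top
5. Training is bitwise reproducible for a fixed seed.

The false-negative machinery can be probed directly. On a seeded
embedding world of 1,000 pairs with ~5% planted false negatives:

```r
rec <- simulate_posterior_recovery(world_config(n_per_class = 250, seed = 101))
#> AUROC = 0.998   mean posterior: planted 0.057, true 0.00007
```

The posterior ranks planted false negatives far above genuine negatives
(AUROC 0.998), which is what lets the sampler avoid pushing semantically
matching pairs apart.

Closed-form components print their expected values directly:

```r
st <- scheduler_state(max_iterations = 20000)   # warm-up = 20000/20 = 1000
warmup_lr(st$warmup_iterations - 1, st)
#> [1] 4e-05
```

A thin command-line wrapper over these functions is installed at
`inst/cli/cmrice.R` (subcommands `train`, `evaluate`, `simulate`,
`schedule-dump`, `make-synthetic`).

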