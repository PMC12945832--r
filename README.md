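# glioscope

Non-invasive subtyping of adult-type diffuse glioma from a single
preoperative axial T2-weighted MRI slice is an attractive alternative to
biopsy: molecular markers (IDH mutation, 1p/19q codeletion) define the
clinically relevant subtypes, and they leave visible traces in tumor
texture, margin sharpness and signal intensity. `glioscope` is a complete,
desk-scale re-implementation of such a pipeline for R: a small MnasNet-style
convolutional network whose hyperparameters are tuned by a single-candidate
metaheuristic, together with everything needed to exercise it end to end —
contrast enhancement, augmentation, leakage-guarded evaluation, and a
synthetic T2-like phantom generator that stands in for the restricted
clinical cohort.

## What is inside

**Optimizers.** The Single Candidate Optimizer (SCO) evolves one solution
through two phases with a decaying step weight
`w(t) = exp(-(b t / T)^b)`:

- phase 1 (global): `x_j = gbest_j ± w |gbest_j|`
- phase 2 (local): `x_j = gbest_j ± r2 w (ub_j - lb_j)`
- stagnation escape after `m` non-improving evaluations:
  `x_j = gbest_j ± r3 (ub_j - lb_j)`

Out-of-bound coordinates are reset to the global best, and acceptance is
greedy. The advanced variant (ASCO) adds opposition-based initialization
(`x̂ = lb + ub - x`, keep the better of the pair) and replaces the uniform
initialization draws with a Chebyshev chaotic stream
`r ← cos(β arccos r)`, β = 0.8, with a collapse guard (at β < 2 the map is
contractive, not chaotic; the stream re-seeds when it reaches its fixed
point).

**Network.** A 3×3 stem and three mobile inverted bottleneck (MBConv)
blocks — 1×1 expansion, depthwise 3×3 convolution, squeeze-and-excitation
gating, linear projection, residual where shapes allow — then global average
pooling, dropout, and a softmax head. Forward *and* backward passes are
implemented in pure R on (H, W, N, C) arrays with BLAS matrix products;
gradients are verified against central differences to 1e-4. Training is SGD
with classical momentum, L2 weight decay, per-epoch exponential LR decay,
and Xavier/He initialization.

**Composite loss.** Candidates are scored by
`L_total = L_CE + λ1·R_latency + λ2·R_params`, where `R_params` is the exact
parameter count (millions) and `R_latency` a deterministic
multiply-accumulate proxy (MMACs); the published selected coefficients are
λ1 = 8.7e-3, λ2 = 4.2e-4.

**Evaluation.** Sensitivity, precision, specificity, F1, accuracy and the
Matthews correlation coefficient; patient-level stratified 80/10/10
splitting (533 patients → exactly 426/54/53) and stratified 10-fold
cross-validation; hard errors on any train/test contamination, including
normalization statistics computed off the training partition.

## Worked example

```r
library(glioscope)

## optimizer benchmark: 10-D sphere
sp  <- search_space(rep(-5, 10), rep(5, 10))
res <- run_asco(bench_sphere, sp, sco_config(T = 5000, seed = 1))
res$f_gbest
#> [1] 0

## phantoms -> split -> CLAHE -> normalize -> train -> evaluate
ds <- make_dataset(phantom_spec(seed = 42))            # 600 synthetic slices
s  <- stratified_split(ds$manifest$patient_id, ds$manifest$label, seed = 1)
ds <- apply_split(ds, s)
for (i in seq_len(600)) ds$images[, , i] <- clahe(ds$images[, , i])
st <- channel_stats(subset_images(ds$images, which(ds$manifest$split == "train")),
                    partition = "train")
ds$images <- normalize(ds$images, st)

m  <- train_model(model_config(), ds, desk_train_config(epochs = 10, seed = 50))
ev <- evaluate(m, ds, split = "test")
ev$metrics
#>   sensitivity  1.0000
#>   precision    0.8571
#>   specificity  0.8333
#>   f1           0.9231
#>   accuracy     0.9167
#>   mcc          0.8452
print(m)
#> glioscope MBConv model
#>   parameters:    8280 (0.0083 M)
#>   latency proxy: 0.314 MMAC
#>   final epoch:   train loss 0.0171, val acc 0.9333333
```

(Output shown is what the code printed for these exact seeds; the test
partition holds 60 of the 600 phantoms, so every sensitivity/specificity
figure is a ratio of small counts — here all 30 class-1 phantoms and 25 of
30 class-0 phantoms are classified correctly. Ten-fold cross-validation
averages ≈0.99 mean accuracy; see the methods vignette for what that does
and does not establish.)

Hyperparameter search over the 10-dimensional encoded space (learning rate,
weight decay, momentum, dropout, λ1, λ2, batch size, epochs, init scheme,
augmentation policy):

```r
h <- run_hpo("asco", budget = 20, data = ds, seed = 7,
             eval_config = list(max_epochs = 3, max_batch = 32,
                                use_augment = FALSE, seed = 7))
h$best_hp$learning_rate
ab <- run_ablation(ds, budget = 10, seed = 7)   # default vs SCO vs ASCO
ab$table
```

## Command line

```sh
Rscript inst/cli/glioscope.R bench --objective sphere --dim 10 \
    --budget 5000 --seed 1 --algo asco
Rscript inst/cli/glioscope.R simulate --n 600 --seed 42 --out phantoms/
Rscript inst/cli/glioscope.R summarize
```

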