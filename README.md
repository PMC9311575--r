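# danet

Divide-and-attention networks for hematoxylin-and-eosin (H&E) stained
pathology patch classification, implemented natively in R.

H&E staining separates tissue into two visual compartments — hematoxylin
renders nuclei purple-blue, eosin renders cytoplasm and extracellular
matrix pink-red — and pathologists weigh the two differently depending on
the diagnostic question (nuclear pleomorphism drives grading; tissue
architecture drives classification). The DANet encodes this prior
structurally. Given a patch `I_main` and a binary nuclei mask `M`:

```
I_down = M ⊙ I_main          (nuclei only)
I_top  = I_main − I_down     (non-nuclei only)
```

Five convolutional branches — `main`, `down`, `top` plus two fused middle
branches (channel concatenation → 1×1 conv → 3×3 conv) — are pooled by
branch-selection attention

```
z = Σ_k a_k V_k,   a_k = softmax_k( wᵀ tanh(Q V_k) )
```

and trained with a combined objective `λ₁·L_CE + λ₂·L_DCCA`, where the
deep canonical correlation analysis (DCCA) term

```
L_DCCA = −corr(H_main, H_down) − corr(H_main, H_top),
corr(H₁, H₂) = (tr TᵀT)^½,  T = Σ₁₁^{−1/2} Σ₁₂ Σ₂₂^{−1/2}
```

maximizes the canonical correlations between the main branch and each
decomposed view, acting as branch-fusion attention. The package is aimed
at computational-pathology researchers who want a transparent, fully
inspectable reference implementation of this architecture: every forward
and backward pass (convolutions, attention, DCCA gradients, Adam) is
plain R, testable and steppable, with no deep-learning framework behind
it.

Also included: non-overlapping slide tiling with exact-geometry resizing,
the standard augmentation family, confusion-matrix metrics
(accuracy/sensitivity/specificity/F-score, macro one-vs-rest AUC),
majority-voting slide aggregation, and a synthetic H&E generator that
renders elliptical nuclei on textured eosin-like backgrounds with exact
ground-truth masks and a controllable class signal (carried by nuclei
morphology, background texture, or both), so the whole pipeline runs
end-to-end on one CPU in seconds.

## Worked example

```r
library(danet)

# a 3-class synthetic task whose signal lives in nuclei morphology
spec <- synthetic_task_spec(signal_carrier = "nuclei")
ds   <- generate_dataset(spec, n_per_class = 100, seed = 1)
sp   <- split_dataset(ds, 2/3, seed = 1)            # 200 train / 100 test

fit <- train_danet(ds[sp$train],
                   danet_config(num_classes = 3),
                   train_config(seed = 1, epochs = 10, batch_size = 16))

evaluate_danet(fit$model, ds[sp$test])
#> accuracy: 0.9697
#> macro sensitivity: 0.9697  specificity: 0.9848  F-score: 0.9697
#> macro AUC: 0.9991
#> normalized confusion matrix:
#>      [,1]  [,2]  [,3]
#> [1,]    1 0.000 0.000
#> [2,]    0 0.939 0.061
#> [3,]    0 0.030 0.970

round(mean_attention(fit$model, ds[sp$test]), 3)
#>   top  mid1  main  mid2  down
#> 0.003 0.618 0.334 0.001 0.043
```

The model classifies a nuclei-size task at 97% and its attention
downweights the branch that cannot help: the nuclei-related mass
(`down` + `mid2`, 0.044) exceeds the non-nuclei branch `top` (0.003),
with the bulk on the fused and original views. On a task whose signal
lives in the background texture (`signal_carrier = "background"`) the
inequality reverses and `top` dominates. That adaptivity — weighting the
decomposed view a task needs — is the point of the architecture, and the
test suite checks the direction of the shift across five seeded
replicates per carrier.

A thin CLI over the same functions lives at `inst/cli/danet`
(`decompose`, `tile`, `synth`, `train`, `evaluate`).

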