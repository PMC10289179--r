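# neuroseg

Weakly supervised 3D neuron segmentation for optical-microscopy volumes —
no manual labels at any stage.

Fluorescence microscopy of labeled neurons (fMOST and related modalities)
produces terabyte-scale 3D stacks in which neurites appear as thin bright
tubes and somata as bright blobs, on a noisy, unevenly lit background.
Training a segmentation CNN on such data normally requires voxel-wise
manual annotation. `neuroseg` bootstraps the labels instead:

1. **Adaptive Hessian enhancement.** The Euclidean distance transform of
   the thresholded volume measures local structure thickness; each voxel
   gets an analysis window of radius `R = clamp(round(log2 DN), 1, 8)`
   (`DN` the distance transform normalized onto [1, 256]). Hessian
   eigenvalues `|λ1| ≤ |λ2| ≤ |λ3|` inside that window feed the line
   response

       O(x) = (1 − e^(−a·p1²)) · e^(−b·p2²) · (1 − e^(−p3²/c)),

   zero whenever `λ2 > 0` or `λ3 > 0`, with `p1 = |λ2|/|λ3|`,
   `p2 = |λ1|/√|λ2λ3|`, `p3² = λ1² + λ2² + λ3²` and defaults `a = 5.55`,
   `b = 2`, `c = 2×10⁶`. Soma interiors (hollowed into rings by any line
   filter) are filled from a second, higher-threshold distance transform.
   Thresholding `O` yields the initial *pseudo-labels*.
2. **Compact 3D encoder–decoder.** Trained from scratch on
   (volume, pseudo-label) patches with the mixed loss
   `L = σ·L_WCE + L_Dice` (SGD, momentum 0.9, lr 0.01, batch 4), with
   augmentation over XY rotations/mirrors and z-flips; prediction is tiled
   sliding-window inference with optional test-time augmentation averaging.
3. **Region growing.** Voxels with probability ≥ 0.5 seed connected
   components; each component's adaptive threshold ρ is the mean
   probability over its 5×5×5 shell, and neighbors with `s(v) > ρ` are
   absorbed to a fixed point, mining weak neurites the filter missed.
4. **Fusion.** `F = α/(α+β)·Θ·I + β/(α+β)·⌊(1−α)·255·P⌋` (α = 0.8,
   screen δ = 2) blends original intensity with the refined probability
   map into the next iteration's input. The loop repeats until the
   double-delta rule `F_t − F_{t−1} < 0.005` and `F_{t+1} − F_t < 0.005`
   fires; the best iteration's probability map binarized at 200/255 is the
   final mask.

A synthetic phantom generator (`generate_phantom()`) produces fMOST-like
volumes — tubular neurites of radius 1–2 voxels with radially decaying
intensity, somata, illumination gradient, Gaussian noise — with exact
ground truth, so the whole pipeline is testable without microscopy data.

## Worked example

```r
library(neuroseg)

ph  <- generate_phantom(phantom_config(seed = 1))   # 64^3, 5 neurites, noise 15
cfg <- loop_config(max_iterations = 3, seed = 1)
run <- run_pipeline(ph$image, ph$mask, cfg, verbose = TRUE)
#> iteration 0: pseudo-label score 0.7746
#> iteration 1: score 0.9840
#> iteration 2: score 0.9856
#> iteration 3: score 0.9886
print(run)
#> Weakly supervised segmentation run
#>   iterations: 3 (best: 2, converged)
#>   score history: 0.7746 0.9840 0.9856 0.9886
#>   final test-split metrics:
#> Voxel-wise segmentation metrics (TP 513, FP 5, FN 10, TN 56816)
#>   precision 0.9903  recall 0.9809  F1 0.9856  Jaccard 0.9716
```

The score history reads: the enhancement filter alone labels the held-out
test slab at F1 0.77; one round of network training, region growing and
fusion lifts it to 0.98; the double-delta rule flags iteration 2 as the
optimum. `run$mask` is the final binary segmentation of the full volume.

Individual stages are plain functions on 3D arrays:

```r
enh  <- enhance_volume(ph$image)        # 0-255 line/soma response
pl   <- make_pseudolabels(enh)          # logical mask
mask <- refine_labels(prob)             # grow a probability map
f    <- fuse_probability(ph$image, prob)
seg_metrics(mask, ph$mask)              # precision/recall/F1/Jaccard
```

A thin command-line wrapper with `phantom`, `enhance`, `refine`, `fuse`,
`evaluate` and `run` subcommands is installed at
`system.file("cli", "neuroseg", package = "neuroseg")`.

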