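# lungscreen

Screening 2-D grayscale chest images for lung carcinoma. The package
implements a complete pipeline — structure-adaptive denoising, lung-field
extraction, metaheuristic-seeded region-growing segmentation, engineered
feature extraction, chi-square feature selection, a residual-network
classifier with parametric ReLU, and a high/low risk screen — together
with a synthetic chest-phantom generator that provides full ground truth,
so every stage is testable without any external imaging data.

It is aimed at researchers who want a reproducible, fully inspectable
reference implementation of this style of classical-plus-learned CT
screening pipeline, and at method developers who need a controlled
phantom world to probe individual stages.

## The method

Given an image `I` with intensities in [0, 1]:

1. **I-ADF denoising.** Anisotropic diffusion `dI/dt = div(D ∇I)` whose
   tensor eigenvalues follow the ladder `α₁ = 1 − C`,
   `α₂ = α₁ + (3/2)(1 − C_planar)`, `α₃ = α₂ + 3(1 − C_linear)`, with
   gains `C = exp(−Var/(k²⟨I⟩² + ε))` computed from intra-class variance
   over structure-tensor–aligned stencils (full 5×5 window, 5×5 planar
   stencil, 7-sample linear stencil). The explicit-Euler scheme is
   conservative (zero-flux boundaries) and checks its stability bound
   `dt ≤ 1/(2·d·max α)`.
2. **Lung-field extraction.** Percentile contrast stretch, multi-level
   Otsu thresholding, and the union of per-lung convex hulls; unsharp
   masking `E = L + η(L − G_σ * L)` enhances boundaries.
3. **B-RGS segmentation.** One coati-optimization run per lung-field
   quadrant picks a knuckle seed (Bates-distributed random steps, greedy
   iguana-hunt and predator-escape phases); a region is grown from each
   seed with threshold `3·sd(5×5 at seed) + 0.05`, giving the four-part
   segmentation `Seg = [Seg(1), …, Seg(4)]`.
4. **Features.** Per quadrant: gradient-histogram block (mode spacing and
   areas, skewness g₁, kurtosis b₂, bimodality (g₁²+1)/b₂), spectral
   flatness (GM/AM of Fourier magnitudes), profile block (rib-cross,
   peak ratio, slope ratio min(diff)/max(diff), slope smoothness), on-rib
   block (centroid-to-rib distance vs inter-rib spacing, chain length /
   slope / eccentricity), on-vessel block
   `Vessel1 = len₁·len₂/(H·W)`, `Vessel2 = 1/min dist`, and the
   nodule-candidate peak intensity — 84 features in all.
5. **BD-CST selection.** Features are median-binarized and scored with
   `e(WZ − YX)²/((W+Y)(X+Z)(W+X)(Y+Z))`; the significance level is the
   binomial pmf value `R = C(e,ρ) g^ρ (1−g)^(e−ρ)`.
6. **PResNet + risk screen.** A small residual network
   (conv → p-ReLU → conv blocks with identity skips, max pooling, 2-logit
   head; `prelu(x) = x` for `x > 0`, `Jx` otherwise with learnable `J`)
   classifies Normal/Abnormal; abnormal images are screened high/low risk
   from the on-rib flags and the nodule-candidate intensity.

## A worked example

```r
library(lungscreen)

## an abnormal phantom: one 6-px nodule sitting on a rib band
spec <- phantomSpec(nodules = list(noduleSpec(6, "on_rib")), seed = 7)
ph <- generatePhantom(spec)
ph
#> ChestPhantom 128x128 | class Abnormal | risk high

## preprocess, segment, extract features
pre <- preprocessImage(phantomImage(ph))
seg <- segmentLungs(pre$enhanced, pre$mask, seed = 7)
seg
#> SegmentationResult: 4 regions (TL, TR, BL, BR)
#>   seed (52,40) threshold 0.2454 size 1075
#>   seed (43,84) threshold 0.2950 size 1098
#>   seed (84,36) threshold 0.2722 size 1138
#>   seed (87,86) threshold 0.2950 size 1002

feats <- extractFeatures(seg, pre$enhanced, reference = pre$denoised)
round(feats[c("q4_on_rib_flag", "q4_nodule_peak", "q1_nodule_peak")], 3)
#> q4_on_rib_flag q4_nodule_peak q1_nodule_peak
#>          1.000          0.950          0.804
```

The four seeds are the optimizer-selected knuckle points (row, col), each
anchoring one grown quadrant region of the stated size. The nodule sits in
the lower-right quadrant: `q4_on_rib_flag = 1` says that quadrant's lesion
candidate lies closer to a rib chain than the inter-rib spacing, and its
peak intensity on the denoised scale (0.950, above the 0.8 risk threshold)
is well above the rib-level peak of a nodule-free quadrant (0.804) — this
phantom screens high-risk.

The one-command demonstration generates a phantom corpus, trains, and
evaluates:

```r
res <- runPipeline("demo", config = pipelineConfig(seed = 1))
res$report$metrics$accuracy   # held-out classification accuracy
```

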