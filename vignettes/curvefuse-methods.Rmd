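---
title: "Curvature-guided multiscale fusion: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-guided multiscale fusion: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvefuse)
```

## The problem

Different medical imaging modalities are complementary: CT renders bone
(the skull is hyperdense) but has weak soft-tissue contrast, while
T2-weighted MRI shows bright cerebrospinal fluid and good gray–white
matter differentiation but little bone. Fusion combines a co-registered
pair into one image that keeps the global intensity structure of both
modalities and the sharpest local detail of either. curvefuse implements
a multiscale, curvature-guided approach to this problem together with the
objective quality metrics used to judge it.

## The pipeline

For sources $A$ and $B$ (real-valued matrices on the 0–255 scale, in
pixelwise correspondence):

1. **Decomposition.** Each image is decomposed recursively, from
   $L_0 = I$:
   $$H_i = L_{i-1} - G_\sigma(L_{i-1}), \qquad
     L_i = \downarrow_2\!\big(G_\sigma(L_{i-1})\big),$$
   for $i = 1..L$. $G_\sigma$ is Gaussian smoothing with a deliberately
   large $\sigma$, so each $H_i$ is a broad-band detail residual and the
   terminal $L_L$ carries only the global intensity layout. The default
   operating point is $L = 3$, $\sigma = 20$ px.
2. **Low-frequency fusion.** $F_L = \alpha L_L^A + (1-\alpha) L_L^B$ with
   $\alpha = 0.5$ by default: equal contribution of both modalities to
   brightness and global contrast.
3. **Curvature enhancement.** The level-$L$ detail subbands of *both*
   sources are evolved under mean-curvature flow
   $$\partial_t u = \kappa(u)
     = \nabla \cdot \frac{\nabla u}{\|\nabla u\|_\varepsilon}, \qquad
     \|\nabla u\|_\varepsilon = \sqrt{u_x^2 + u_y^2 + \varepsilon},$$
   by explicit Euler steps with $\Delta t = 0.0005$ for 15 iterations and
   $\varepsilon = 10^{-4}$. The flow shortens level-set curvature — it
   smooths oscillatory noise while leaving straight edge transitions
   (where $\kappa \approx 0$) alone. It is applied before the detail
   fusion rule, symmetrically to both sources.
4. **High-frequency fusion.** Pointwise max-absolute selection:
   $F_{H_i}(x,y)$ is whichever of $H_i^A(x,y)$, $H_i^B(x,y)$ has strictly
   larger magnitude, ties going to the second source. This keeps the
   dominant edge or texture response undiluted, where averaging would
   attenuate opposing coefficients.
5. **Reconstruction.** Coarse to fine: $R_L = F_L$,
   $R_{i-1} = \uparrow_2(R_i) + F_{H_i}$, with $\uparrow_2$ resized to
   the recorded shape of level $i-1$. The single-upsampling closed form
   this telescopes is shape-inconsistent for $L > 1$; the recursive
   reading is the unique shape-consistent one and is what the package
   implements.

A classical Laplacian pyramid backend (5-tap binomial analysis filter
$[1,4,6,4,1]/16$, exact residual storage, hence perfect reconstruction)
is available via `fusion_config(backend = "laplacian_pyramid")` and as
`lp_decompose()` / `lp_reconstruct()`.

### Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `levels` | 3 | – | decomposition depth; deeper adds redundancy and over-smoothing |
| `sigma` | 20 | px | blur scale separating detail from base; large by design |
| `alpha` | 0.5 | – | low-frequency weight on source A |
| `dt` | 0.0005 | – | flow time step (explicit Euler) |
| `iterations` | 15 | – | flow steps; total evolution $15 \times 0.0005$ |
| `epsilon` | 1e-4 | – | gradient-norm stabilizer |
| `filter_scope` | `level_L_only` | – | which detail levels are flow-filtered |
| `high_rule` | `max_abs` | – | detail fusion rule |
| `low_mode` | `both` | – | low-frequency source selection |

With $\Delta t \cdot \text{iterations} = 0.0075$ the total evolution is
small relative to typical curvature magnitudes; the filter is a gentle
regularizer rather than an aggressive denoiser. Strength is fully exposed
through `flow_params()` for users who want more.

## Numerical conventions

These conventions are fixed (and logged by the CLI) because they
materially affect results:

- **Gaussian kernel**: truncated at radius $\lceil 3\sigma \rceil$ and
  renormalized; boundary handling by symmetric half-sample reflection.
  With $\sigma = 20$ the kernel spans 121 taps, so the boundary mode
  shapes the subbands and cannot be left implicit.
- **Resampling**: $\downarrow_2$ is stride-2 sampling from the first
  pixel (smoothing is the anti-alias step; ceiling convention for odd
  sizes); $\uparrow_2$ is bilinear interpolation to the exact recorded
  target shape, placing retained samples back on their original grid.
  Per-level shapes are recorded in the pyramid, removing odd-size
  ambiguity.
- **Exact constants**: separable filtering and resampling are applied to
  the deviation from an anchor value, which is algebraically identical
  but makes constant images round-trip bit-exactly — so fusing an image
  with itself returns it exactly when it is constant, and within 2%
  relative RMSE when it is smooth (measured ~0.05% on noise-free
  phantoms; the residual is resampling aliasing of the heavily blurred
  base, since $\uparrow_2 \circ \downarrow_2$ is not the identity).
- **PDE discretization**: central differences on the interior, one-sided
  at borders, for both the gradient and the divergence; the time stepper
  is explicit Euler (the stated $\Delta t$ and iteration count pin the
  scheme's behavior; nothing implicit is needed at this strength).
  Constants and linear ramps are exact fixed points.
- **Max-abs ties** go to the second image (the strict inequality as
  conventionally printed), fixed for reproducibility; at $\alpha = 0.5$
  swapping the sources changes the output only at exact-tie pixels.
- **Quantization**: histogram-based metrics (entropy, mutual
  information) operate on the round-half-even uint8 quantization of the
  floating images; gradient- and moment-based metrics (AG, SF, API, SD,
  Corr) use the floating image. Fused output is clamped and quantized
  only at export.
- **Weighted MC sign**: `wmc_filter()` steps
  $u \leftarrow u - \Delta t \, w \, \kappa(u)$, so `weight = -1`
  reproduces `mc_filter()` exactly and `weight = 0` is the identity. The
  opposite-signed mean-curvature convention found in parts of the
  literature is a surface-orientation choice; this package's convention
  is documented with the function.

## The metric suite

`fusion_metrics()` reports nine scores. API (mean intensity), SD
(population standard deviation), AG (mean forward-difference gradient
magnitude) and SF (RMS first differences along rows/columns, combined in
quadrature) are no-reference sharpness/contrast scores. Entropy and the
mutual-information family (MIF $= MI(F,A) + MI(F,B)$, fusion symmetry
FS1) are computed from 256-level histograms. Corr reports the mean
Pearson correlation against the two sources (tables in this literature
print a single column, while the definition is pairwise; `mode = "a"` or
`"b"` selects one pairing).

Two conventions deserve comment:

- **AG/SF divisors.** The printed index ranges of these sums run one
  past the array; sums therefore cover valid difference pairs only while
  the printed $1/(MN)$ divisor is kept as the default, with a
  `divisor = "valid"` switch normalizing by the pairs actually summed
  (under which a unit-slope ramp has AG exactly 1).
- **FS1 variant.** The printed symmetry formula
  $(MI(F,A)-MI(F,B))/(MI(F,A)+MI(F,B))$ is bounded by 1, yet published
  comparison tables for this family of methods report values in
  $[1.5, 2]$ — consistent with
  $2 - |MI(F,A)/(MI(F,A)+MI(F,B)) - 0.5|$. The table-consistent form is
  the default (2 = perfectly balanced); the printed form remains
  available via `variant = "printed"`.

**QAB/F** is the standard Sobel-based edge-information preservation
measure: per pixel, relative gradient strength and orientation between
each source and the fused image are squashed through sigmoids with the
literature constants (strength $\Gamma=0.9994, \kappa=-15, \sigma=0.5$;
orientation $\Gamma=0.9879, \kappa=-22, \sigma=0.8$) and averaged,
weighted by source edge strength. Each sigmoid is normalized by its
value at perfect preservation so that a perfectly preserved edge scores
exactly 1 (the raw sigmoids saturate slightly below 1); this makes
`metric_qabf(A, A, A) == 1` a hard identity rather than an
approximation, at the cost of scores sitting ~2% above the
unnormalized convention. Orientation uses the gradient component ratio,
which makes the score exactly invariant to simultaneous intensity
negation of all three images.

## The synthetic phantoms

`make_phantom_pair()` generates the study conditions for all shipped
tests: a 256×256 co-registered pair in which image A is MRI-like
(smooth Gaussian soft-tissue blobs on a 90-intensity interior, a bright
central fluid ellipse at 200 emulating CSF, dark skull ring) and image B
is CT-like (hyperdense skull ring at 230, flat 70-intensity interior),
both with additive Gaussian noise of 2 intensity units, generated under
an explicit seed with no global RNG side effects. Geometry is shared, so
the pair is exactly co-registered; the modalities are genuinely
complementary (pixel correlation ≈ 0.04; in the noise-free CT image
all of the gradient energy lies within 3 px of the ring).

What the phantoms do *not* emulate: anatomy-scale texture statistics,
modality-specific noise (Rician MRI noise, CT streaking), partial-volume
effects, intensity nonuniformity and registration error. Passing tests
therefore demonstrate the *mechanics* of the pipeline — decomposition
identities, rule behavior, metric definitions, directional ablation
trends — not clinical image quality; on clinical data the quantitative
scores will differ, and only the implemented conventions carry over.

Problem sizes in the shipped tests and the acceptance script (256×256
phantoms, 20-seed ablation replicates, 50 32×32 Laplacian round-trips,
4×4 oracle images) were chosen as the smallest sizes at which each
property is meaningfully exercised — e.g. 256×256 is the smallest canvas
on which a σ=20 blur produces a non-degenerate three-level pyramid.

## Design choices where the design was open

- The decomposition is implemented exactly as its defining recursion
  states: a Gaussian residual pyramid with no directional stage.
  A directional filter bank would refine each $H_i$ into oriented
  wedges, but no step of the fusion recursion produces or consumes
  directional subbands, so none is included (see Non-goals).
- Two pyramid backends are provided rather than reconciled: the
  preliminaries' Laplacian ordering (smooth, decimate, interpolate,
  subtract — exact) and the method's ordering (subtract the blur before
  decimating — near-exact). They differ in where the residual is taken;
  the fusion defaults use the latter.
- Whether one or both sources' level-$L$ subbands are filtered is not
  pinned down by the method description; filtering both is the symmetric
  default and keeps $A \leftrightarrow B$ exchange symmetry at
  $\alpha = 0.5$.
- The weight map of the weighted-MC variant is accepted as caller input
  (scalar default −1) rather than guessed: the variant's defining
  publication leaves $w(x,y)$ application-specific.
- The ablation suite reproduces the two published degradations (weighted
  detail averaging; single-source low band) plus the full method, as a
  four-row tidy table, because the directional claims — max-abs beats
  weighted averaging on SF and QAB/F — are the part of the evaluation
  that transfers to synthetic data.

## Known limitations

- 2-D, single-channel, two sources only; PET/SPECT color studies must be
  collapsed to grayscale first. No registration: inputs must already be
  in pixelwise correspondence (only shape equality is checked).
- The Gaussian-residual scheme is not perfect-reconstruction; error is
  bounded in practice (~0.05% relative RMSE on smooth 256×256 content)
  but grows if `sigma` is made small relative to image structure, since
  decimation then aliases.
- Explicit Euler limits how far the curvature flow can be pushed:
  stability requires small $\Delta t$; the defaults are far inside the
  stable regime.
- Dense operator matrices make filtering $O(n^2)$ memory per dimension
  pair; ample for the intended image sizes (≤ ~1k pixels per side), not
  for volumes.

```{r example}
pair <- make_phantom_pair(phantom_spec(seed = 1))
fused <- fuse_images(pair$a, pair$b)
fusion_metrics(fused, pair$a, pair$b)
ablation_suite(pair$a, pair$b)[, c("variant", "SF", "QABF")]
```
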