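# curvefuse

Structure-aware fusion of co-registered multimodal medical image pairs
(e.g. MRI + CT of the same brain slice), with the complete objective
quality metric suite used to evaluate fusion methods.

## Who it is for

Medical imaging researchers who need a reproducible, scriptable
implementation of multiscale curvature-guided fusion and of the standard
fusion-quality scores (API, SD, AG, Entropy, MIF, FS1, Corr, SF, QAB/F)
— either as an R library or as a command-line tool.

## The method

For co-registered sources *A*, *B* (grayscale, 0–255 scale):

1. **Multiscale decomposition** (L = 3 levels): from L₀ = I,

   Hᵢ = Lᵢ₋₁ − G_σ(Lᵢ₋₁),  Lᵢ = ↓₂(G_σ(Lᵢ₋₁)),

   with heavy Gaussian smoothing (σ = 20 px) separating broad-band detail
   subbands Hᵢ from the terminal low-frequency image L_L.
2. **Low-frequency fusion** by weighted averaging:
   F_L = α·L_L^A + (1−α)·L_L^B, α = 0.5.
3. **Mean-curvature enhancement** of the level-L detail subbands of both
   sources: ∂u/∂t = κ = ∇·(∇u/‖∇u‖_ε), explicit Euler with
   Δt = 0.0005 for 15 iterations (ε = 10⁻⁴).
4. **High-frequency fusion** by the max-absolute selection rule:
   keep the coefficient of larger magnitude at every pixel.
5. **Coarse-to-fine reconstruction**: R_L = F_L,
   Rᵢ₋₁ = ↑₂(Rᵢ) + F_Hᵢ.

A classical exact-reconstruction Laplacian pyramid backend, TV /
Gaussian-curvature / weighted-MC filter variants, and a deterministic
synthetic MRI-like/CT-like phantom generator are included.

## Worked example

```r
library(curvefuse)

pair  <- make_phantom_pair(phantom_spec(seed = 1))  # MRI-like a, CT-like b
fused <- fuse_images(pair$a, pair$b)                # published defaults
fusion_metrics(fused, pair$a, pair$b)
#>     API   SD    AG Entropy   MIF   FS1  Corr    SF   QABF
#> 1 75.67 87.1 11.52   5.418 3.877 1.891 0.673 34.17 0.6761
```

Reading the row: the fused phantom keeps high contrast (SD 87) and sharp
detail (SF 34.2, AG 11.5) while drawing information almost evenly from
both modalities (FS1 1.89 on the \[1.5, 2\] balance scale; MIF 3.88 bits
of retained source information). QAB/F 0.68 means about two-thirds of
the sources' edge strength/orientation information survives into the
fused image.

The ablation suite shows why the defaults matter — replacing max-abs
detail selection by plain averaging halves SF and QAB/F, and dropping
one source's low band shifts brightness (API) while detail scores stay:

```r
ablation_suite(pair$a, pair$b)[, c("variant", "API", "SD", "SF", "QABF")]
#>         variant   API    SD    SF   QABF
#> 1          full 75.67 87.10 34.17 0.6761
#> 2 weighted_high 65.19 46.56 15.93 0.3795
#> 3    low_a_only 66.62 87.69 34.17 0.6761
#> 4    low_b_only 84.73 86.53 34.17 0.6760
```

## Command line

```sh
curvefuse=$(Rscript -e 'cat(system.file("exec", "curvefuse", package = "curvefuse"))')
Rscript "$curvefuse" demo --seed 7 --out demo/            # phantom pair + fusion + report
Rscript "$curvefuse" fuse --a A.png --b B.png --out F.png --report F.json
Rscript "$curvefuse" metrics --fused F.png --a A.png --b B.png --report m.json
Rscript "$curvefuse" ablate --a A.png --b B.png --report ablation.csv
```

All flag defaults equal the method's published parameters; INFO logging
records every parameter and convention in effect.

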