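# echomap

Mapping extraction from multiecho T2\*-weighted MRI.

In a multiecho gradient-echo acquisition the same slice is imaged at `n`
ascending echo times, so every pixel carries a decay curve
`V = (V_1, ..., V_n)` following the monoexponential signal model
`V_k ≈ W · exp(−TE_k / T2*)`. Classical similarity coefficient mapping
(SCM) scores each pixel by the single scale factor relating its curve to a
reference decay curve `R`. `echomap` implements the two-parameter extension
of that idea: per pixel, ordinary least squares of `V` on `R`,

```
MSE = (1/n) Σ_k (V_k − λ R_k − ξ)²
λ = ( mean(V·R) − mean(V)·mean(R) ) / ( mean(R²) − mean(R)² )
ξ = mean(V) − λ · mean(R)
```

The slopes `λ` form the **signal-strength map (SSM)** and the intercepts
`ξ` the **fluctuation-magnitude map (FMM)**. A pixel whose curve equals the
reference gets `λ = 1, ξ = 0`; tissues whose decay differs from the
reference separate in `(λ, ξ)` space, which is what makes fine structures
such as veins stand out on both maps.

The reference is a model curve `R_k = W · exp(−TE_k / T2*)`. Rather than
requiring a manually delineated ROI, the reference T2\* is chosen
automatically by maximizing `CI(SSM) + CI(FMM)` over a grid (1–120 ms by
default), where CI is a no-reference windowed contrast index: the mean over
all interior 7×7 windows of `|m_f − m_b| / (m_f + m_b)` with `m_f` the
centre pixel and `m_b` the mean of the other window pixels. `W` is set to
80 % of the maximum stack intensity; the objective is provably invariant to
`W`, so this only fixes the output scale. Contrast gains are summarized by
the contrast improvement index `CII = CI_map / CI_ori`.

The package is aimed at quantitative-MRI researchers who want SSM/FMM maps
plus the standard baselines (SCM, log-linear T2\* mapping), a synthetic
multiecho phantom with known ground truth for validation, NIfTI I/O with
JSON echo-time sidecars, and a command-line pipeline.

## Worked example

```r
library(echomap)

spec <- vein_phantom_spec(seed = 20260923)   # 96x96 brain-like phantom
ph   <- generate_phantom(spec)               # stack + ground truth

opt <- optimize_reference(ph$stack)          # T2* grid search, 1..120 ms
opt$trace
#> <optimization_trace> 120 candidates, T2* 1 .. 120 ms
#>   best T2* = 48 ms (objective 0.6926), W = 78.69

fit <- fit_ssm_fmm(ph$stack, opt$reference)
scm <- fit_scm(ph$stack, opt$reference)
contrast_report(ph$stack, list(SCM = scm, SSM = fit$ssm, FMM = fit$fmm))
#> <contrast_report>
#>   CI per image:
#>     echo_01  0.1797
#>     ...
#>     echo_12  0.1988
#>     SCM      0.1412
#>     SSM      0.3202
#>     FMM      0.3725
#>   mean CII over echoes:
#>     SCM      0.7436
#>     SSM      1.6857
#>     FMM      1.9612
```

The sweep lands on T2\* = 48 ms — exactly the decay constant of the
phantom's dominant tissue. CI rises slowly across the 12 original echoes
(0.180 → 0.199), SCM *loses* contrast relative to the originals
(mean CII 0.74), while SSM and FMM gain it (1.69 and 1.96): the derived
maps out-contrast every original echo, and the fluctuation map gains most.
The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "echomap.R", package = "echomap"))')
CFG=$(Rscript -e 'cat(system.file("extdata", "vein_phantom.yaml", package = "echomap"))')
Rscript "$CLI" phantom  --config "$CFG" --out run/
Rscript "$CLI" optimize --input run/stack.nii.gz --out run/
Rscript "$CLI" contrast --input run/stack.nii.gz \
        --maps run/scm.nii.gz,run/ssm.nii.gz,run/fmm.nii.gz --out run/
```

which writes the maps as NIfTI, the T2\* sweep as `trace.csv` and the
CI/CII tables as `contrast.csv`.

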