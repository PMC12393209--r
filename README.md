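# cardiodki

Simulation and estimation for **diffusion kurtosis imaging (DKI) of the
human heart**.

Cardiac diffusion MRI at routine b-values (≤ 450 s/mm²) is well described
by a Gaussian (tensor) model, but at higher diffusion weightings the signal
of myocardium departs from mono-exponential decay because membranes and
organelles restrict water displacement. cardiodki implements the complete
analysis chain for quantifying that departure — and, because in-vivo raw
data for such studies are rarely deposited, a fully synthetic short-axis
left-ventricle study generator against which every step is validated. It is
aimed at researchers developing or stress-testing cardiac DKI pipelines:
protocol layout, noise propagation, estimator behaviour, and the statistics
reported in a volunteer study can all be reproduced from seeds alone.

## The model

The signal along encoding direction **n** at weighting *b* follows the
cumulant expansion truncated at the kurtosis term:

    ln S(n, b) = ln S0 − b Σ nᵢnⱼ Dᵢⱼ + (1/6) b² MD² Σ nᵢnⱼnₖnₗ Wᵢⱼₖₗ

with diffusion tensor `D` (6 unique elements), fully symmetric kurtosis
tensor `W` (15 unique elements) and `MD = tr(D)/3` — 22 linear parameters,
estimated by two-pass weighted linear least squares on the log-signal
(weights = squared predicted signals). Derived maps: MD, FA, mean / axial /
radial kurtosis (MK, AK, RK), helix angle (HA) and secondary eigenvector
angle (E2A).

The package covers:

* five-shell acquisition schemes (b = 100…1350 s/mm², electrostatic-
  repulsion directions) with FSL-style `.bval`/`.bvec` I/O;
* a synthetic LV phantom whose per-voxel tensors are constructed in closed
  form so the global MD/FA/MK/AK/RK hit prescribed targets exactly, with a
  transmural helix-angle ramp, complex-valued synthesis (motion-like phase,
  Gaussian noise tuned to an SNR ladder), noise-only frames and seeded
  whole-frame dropouts;
* preprocessing: phase-corrected real-valued reconstruction, noise/SNR
  estimation, robust outlier rejection;
* WLS DTI/DKI fitting, scalar and angle maps, NIfTI export;
* study-level statistics: MD-vs-bmax subset fits, DTI-vs-DKI subset
  comparison, 1-D mono-exponential vs kurtosis curves, Bland–Altman,
  exact Wilcoxon signed-rank, an echo-time SNR-gain calculator, and a
  deterministic 10-subject synthetic study.

Everything user-facing takes and returns tibbles; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` / `plot_*()` figures.

## Worked example

```r
library(cardiodki)

spec   <- phantom_spec(seed = 101)             # default LV phantom
truth  <- build_ground_truth(spec)
scheme <- cardiac_dki_protocol(seed = 101)     # 756 measurements, 5 shells

series <- synthesize_series(truth, scheme, snr = Inf) |>  # noiseless
  phase_correct_real()

run_bmax_subset_analysis(series)
#> # A tibble: 4 × 6
#>    bmax n_voxels md_mean    md_sd fa_mean    fa_sd
#>   <dbl>    <int>   <dbl>    <dbl>   <dbl>    <dbl>
#> 1   450      476    1.58 0.000202   0.307 0.000244
#> 2   900      476    1.51 0.000367   0.301 0.000647
#> 3  1200      476    1.47 0.000647   0.297 0.00123
#> 4  1350      476    1.45 0.000871   0.296 0.00167

maps <- fit_dki_wls(series, scheme) |> dki_scalar_maps()
colMeans(maps[maps$ok, c("md", "fa", "mk", "ak", "rk")])
#>      md      fa      mk      ak      rk
#> 0.00166 0.31000 0.32000 0.27000 0.35000
```

The first table shows the hallmark of non-Gaussian diffusion: the
tensor-model MD falls from 1.58 to 1.45 ×10⁻³ mm²/s as the maximum b-value
rises from 450 to 1350 s/mm², because the ignored kurtosis term bends the
log-signal upward. The second line shows that the full kurtosis fit
recovers the phantom's generating global metrics exactly (MD in mm²/s).

A noisy multi-subject study with group statistics:

```r
study <- run_full_study(study_config(n_subjects = 10,
                                     analyses = "kurtosis", seed = 20))
study$rk_minus_ak
#> # A tibble: 1 × 6
#>     mean      sd p_value method loa_lower loa_upper
#>    <dbl>   <dbl>   <dbl> <chr>      <dbl>     <dbl>
#> 1 0.0868 0.00960 0.00195 exact     0.0680     0.106
```

Radial kurtosis exceeds axial kurtosis (more restriction across than along
the myocytes); the paired difference is significant at the smallest exact
two-sided p attainable with ten subjects.

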