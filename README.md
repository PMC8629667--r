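# wcbaseg

Lung tumor segmentation in 2-D CT slices by a dictionary-based deformable
model with a hybrid water-cycle/bat metaheuristic, written for researchers
who need a fully scripted, seed-reproducible segmentation chain they can
dissect stage by stage.

The pipeline:

1. **Median filter** — exact order-statistic denoising (odd window,
   replicate or reflect borders), removing impulse noise from the slice.
2. **Lung lobe extraction** — Bayesian fuzzy clustering: pixel intensities
   follow a fuzzy mixture of `O` Gaussian prototypes `t_w` with memberships
   `m_w ∝ (π_w N(x; t_w, σ))^(1/(f−1))` under a symmetric Dirichlet prior;
   alternating MAP sweeps update memberships and prototypes
   (`t_w = Σ m^f x / Σ m^f`) and the best-posterior sweep is kept. A
   border-aware heuristic turns the darkest interior clusters into a lobe
   mask (or supply your own).
3. **Dictionary-based deformable model** — all `T×T` patches are k-means
   clustered into `d` atoms; a sparse biadjacency matrix `G` links pixels to
   the dictionary pixels of every covering patch. Labels are pushed to the
   dictionary as frequencies `g = diag(G'1)⁻¹ G'C`, area-normalized
   (`g̃_x ∝ g_x/|A_x|`), pulled back as probabilities
   `E = diag(G1)⁻¹ G g̃`, sharpened by `Ẽ_x = e_x/(e_x + max_{n≠x} e_n)`,
   and drive a level set
   `∂φ/∂t = (1/2 − Ẽ + w·κ + F_region)‖∇φ‖` (inside = `{φ < 0}`).
4. **Curve update** — plain explicit Euler, or the bat-blended stochastic
   update `φ' = D/(D−l_b)·[Δt·∂φ/∂t − rand·z·l_b(φ_prev + Q)/D]` with
   `D = 1 − rand·z(2 − l_b)` and random bat frequency
   `l_b = l_min + (l_max − l_min)k`, applied as a keep-if-better proposal.

The same water-cycle/bat algebra is exposed as a standalone box-constrained
optimizer (`wcba_optimize()`): a population of raindrops with sea/river/
stream roles, stream flow toward cost-proportional guides, evaporation and
raining restarts, and a geometrically decaying evaporation radius.

A seeded phantom generator (`phantom_spec()`, `phantom_suite()`) supplies
lung-like textured slices with exact ground-truth masks in three
conditions — intensity-contrast tumor, equal-mean texture-only tumor, and
5% impulse noise — plus the standard overlap metrics (accuracy, Jaccard,
Dice) for evaluation.

## Worked example

```r
library(wcbaseg)

spec <- phantom_suite(seed = 1)$easy          # 128x128 phantom slice
res  <- run_pipeline(spec, pipeline_config(seed = 1))
res$metrics
#>    tp    tn fp fn  accuracy   jaccard      dice
#> 1 324 15999 61  0 0.9962769 0.8415584 0.9139633
```

The pipeline found all 324 tumor pixels (`fn = 0`) with 61 false positives
on the 128×128 slice: pixel accuracy 0.996, Jaccard overlap 0.84, Dice 0.91
against the phantom's exact ground truth. `res$tumor_mask` and
`res$lobe_mask` are binary matrices; `res$log` records per-stage parameters
and timings.

The standalone optimizer on a 5-D shifted sphere (bounds ±10):

```r
r <- wcba_optimize(benchmark_objective("sphere", shift = 3),
                   wcba_params(n_vars = 5, lower = -10, upper = 10, seed = 1))
r$best_cost
#> [1] 0.0003568499
round(r$best_position, 4)
#> [1] 2.9876 3.0033 2.9994 2.9946 3.0128
```

A thin command-line front end with `preprocess`, `lobes`, `segment`,
`pipeline`, `phantom`, `optimize` and `benchmark` subcommands is installed
at `inst/cli/wcbaseg`.

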