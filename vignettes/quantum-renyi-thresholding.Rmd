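---
title: "Quantum and classical Rényi entropy for 2D-histogram multilevel thresholding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum and classical Rényi entropy for 2D-histogram multilevel thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrseg)
```

## The model

Multilevel thresholding picks `k` gray levels that split an image's
intensity range into `k + 1` classes, each rendered by one representative
level. One-dimensional entropy criteria see only the intensity histogram;
`qrseg` works on the Abutaleb-lineage **2D histogram** instead: for every
pixel we compute the mean of its 3×3 neighbourhood (restricted to in-bounds
pixels — 4 at corners, 6 on edges, 9 in the interior), round it half-up to
an integer bin, and count joint occurrences `h(x, y)` of intensity `x` and
local mean `y`. Homogeneous regions pile up near the diagonal `x ≈ y`;
edges and impulse noise land off-diagonal. Candidate thresholds
`X = (t1 < … < tk | v1 < … < vk)` tile the diagonal with `k + 1` rectangles
`DRi`, and only the mass inside these rectangles is scored — discarding
off-diagonal mass is what buys noise robustness.

Two objectives score a partition, both built from the globally normalized
weights `w(x, y) = h(x, y)/MN`:

* **Classical Rényi** of order `α`:
  `CRα(DRi) = (1/(1−α)) ln Σ w(x,y)^α`, summed over the rectangle's cells.
* **Quantum Rényi**: each cell is an FRQI qubit `cos θ|0⟩ + sin θ|1⟩`,
  `θ = (π/2) w(x,y)`. A rectangle's state is the (unnormalized) sum of its
  cell states, with amplitude sums `C = Σ cos θ`, `S = Σ sin θ` and density
  operator `ρ = (C,S)(C,S)ᵀ`. Then
  `QRα(DRi) = (1/(1−α)) ln trace(ρ^α)`, with `trace(ρ^α)` evaluated through
  the spectral decomposition of the symmetric 2×2 `ρ` under the convention
  `0^α = 0`. Because `ρ` has rank one, its nonzero eigenvalue is `C² + S²`,
  so `QRα(DRi) = (α/(1−α)) ln(C² + S²)` — an identity the test suite checks
  to 1e-9 against the eigendecomposition path.

The total fitness is the sum over the `k + 1` rectangles, maximized over
`X`. The optimal **row** thresholds `t*` reconstruct the output image:
class `i` collects pixels in `[t(i−1)+1, ti]` (the threshold belongs to the
class below it, exactly mirroring the rectangle tiling), and each class is
replaced by the rounded mean of its members. Column thresholds `v*`
influence the fitness only; this asymmetry is inherent to the
diagonal-rectangle objective and is preserved deliberately.

## Interpreting the two objectives

With the literal, unnormalized `ρ` the quantum entropy of a rectangle is a
monotone function of `C² + S²`, which grows with both the rectangle's area
(every zero-weight cell contributes `cos 0 = 1` to `C`) and the mass inside
it. Trace-normalizing `ρ` would make every non-empty subsystem a pure state
with `QRα = 0` identically, destroying the fitness signal — which is why
`rho_normalization = "literal"` is the default and `"unit_trace"` exists
only for study. Likewise `empty_cell_policy` controls whether zero-count
cells enter the amplitude sums: `"all_cells"` is the default (the
rectangle-as-subsystem reading), `"occupied_only"` is provided because the
literal reading makes the objective depend strongly on rectangle area. For
the classical objective the policies coincide, since `0^α = 0` for `α > 0`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.01 | Rényi order; values below 1 emphasize probable cells. The default is the setting used in the reference experiments. |
| `k` | — | number of thresholds; classes are `k + 1`. |
| `population` | 30 | swarm/population size for PSO and DE. |
| `max_iterations` | 1000 | iteration budget. |
| `de_mutation_F`, `de_crossover_CR` | 0.8, 0.9 | DE/rand/1/bin operators. |
| `pso_c1`, `pso_c2` | 2, 2 | cognitive/social coefficients. |
| `pso_inertia_start/end` | 0.9 → 0.4 | linear inertia schedule across the full iteration budget. |
| `stagnation_patience` | 100 | stop after this many iterations without global-best improvement. |

The stagnation rule is this package's own termination criterion: the source
experiments report mean iteration counts far below the budget but do not
state their stopping rule, so iteration counts here are not comparable to
theirs. Every result records the iterations actually used.

## Numerical and design choices

* **Search representation.** PSO and DE move in the continuous box
  `[1, L−2]^{2k}`; every evaluation goes through a repair step (round, clip,
  sort, resolve duplicates by cascaded increments with a downward sweep at
  the top of the range), so each scored candidate is a valid strictly
  increasing integer vector. This round-and-repair relaxation is standard
  practice for integer thresholding with these optimizers.
* **Fast fitness.** The optimizers evaluate candidates through 2D prefix
  sums of `w^α` (classical) or of the cell-angle cosine/sine matrices
  (quantum), making one candidate cost `k + 1` constant-time rectangle
  lookups. `classical_renyi()` / `quantum_renyi()` are the direct
  per-rectangle reference implementations, and the suite asserts the two
  routes agree to 1e-9 across modes and policies.
* **Degenerate candidates.** A rectangle with zero weight-power sum or
  `C² + S² = 0` has no defined entropy; the whole candidate receives the
  finite penalty sentinel −1e12 instead of −∞, keeping the metaheuristics'
  arithmetic safe while strictly dominating every feasible value.
* **Ties.** Exhaustive search breaks fitness ties toward the
  lexicographically smallest `(t | v)`; the metaheuristics do the same when
  an equal-fitness candidate is seen. PSO velocities are clamped to
  `±(L−3)/2` per dimension and positions reflect at the bounds.
* **Rounding.** Local means and class means round half-up (R's `round()`
  is banker's rounding); the rounding rule for fractional local means is a
  convention this package fixes, not one inherited from the method's
  formulation.
* **Boundary convention.** A threshold value belongs to the class/rectangle
  *below* it everywhere — `DR1 = [0, t1] × [0, v1]` and class 1 = `[0, t1]`.
  Keeping one convention for both the objective and the reconstruction makes
  noiseless two-level images reconstruct exactly for every optimal
  threshold, which the suite tests end to end.
* **Enhancement hook.** `enhance_contrast()` offers identity (default),
  global histogram equalization, and CLAHE via EBImage. Quality metrics are
  computed against the image actually segmented (the enhanced image when
  enhancement is on); comparing to the raw original is available via
  `run_benchmark(compare_to = "original")`.

## The quality metrics

The nine-metric report fixes explicit formulas (PSNR with a 100 dB cap at
zero MSE; SSIM over 8×8 sliding windows with constants `(0.01·255)²` and
`(0.03·255)²`; AMBE; CII as the ratio of mean 3×3 local contrasts with an
ε = 1e-9 guard; population SD; edge density as the fraction of Sobel
magnitudes above Otsu's threshold of the magnitude image; REC as relative
1D Shannon-entropy change; spatial frequency; CIR over positive-contrast
windows). These are standard constructions chosen and documented here as
the package's contract: values are comparable within this package, but not
guaranteed to match numbers produced under other metric variants. All
metrics except AMBE read higher-is-better, which is also the direction
vector the ranking harness uses.

## What the synthetic fixtures do and do not show

`make_piecewise_image()` emulates what the 2D-histogram method exploits in
real images: spatially contiguous classes (horizontal bands, so local means
stay informative), well-separated class means, and additive Gaussian noise
clipped to the 8-bit range. Fixture defaults — 128×128 pixels, class means
(60, 128, 200), σ = 8, equal fractions — give a 68/σ ≈ 8.5 standard
deviation gap between adjacent means, a regime where threshold recovery
should be essentially certain and is verified at ≥ 18/20 seeded runs. The
fixtures deliberately do **not** contain texture, gradients, curved region
boundaries, or correlated noise; passing the recovery tests therefore
demonstrates correctness of the machinery, not segmentation quality on
natural scenes. For method comparison on real data, `run_benchmark()`
accepts arbitrary image files.

Benchmark-scale choices in the tests and acceptance script (random
histograms at `L = 32` with `k = 2` for the exhaustive-oracle comparison —
about 1.9 × 10⁵ candidates — and 100–1000-case property sweeps) are sized so
the whole suite runs in minutes on a single core while still exercising
every code path at full parameter defaults.

## Known limitations

* Only the row thresholds shape the output image; the column dimension
  regularizes the objective but cannot move class boundaries on its own.
* The literal quantum objective depends on rectangle area as well as mass;
  at `α` near 0 the area term dominates and the QR fitness surface becomes
  flat over large regions — the `occupied_only` policy is the built-in probe
  for this behaviour.
* Iteration counts depend on the stagnation rule and are not comparable
  across termination conventions.
* Images are processed as full `L × L` histograms; `L` is configurable for
  reduced-gray-level studies, but windows other than 3×3 are intentionally
  not supported.
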