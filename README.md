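# qrseg — multilevel image thresholding with quantum and classical Rényi entropy

`qrseg` segments 8-bit grayscale images — microscopy fields, radiographs,
benchmark photographs — into `k + 1` intensity classes by maximizing an
entropy objective on the image's **two-dimensional histogram**: the joint
distribution `h(x, y)` of each pixel's intensity `x` and the rounded mean
`y` of its 3×3 neighbourhood. Using the local mean as a second axis makes
thresholding robust to isolated noise pixels, which land off the histogram's
main diagonal and are ignored by the objective.

## The method

A candidate solution is a pair of strictly increasing threshold vectors
`X = (t1 < … < tk | v1 < … < vk)` that carve the diagonal of the `L × L`
histogram into `k + 1` **diagonal rectangles** `DRi` — `[0,t1] × [0,v1]`,
`[t(i−1)+1, ti] × [v(i−1)+1, vi]`, …, up to `[tk+1, L−1] × [vk+1, L−1]`.
Each rectangle is scored in one of two ways, both with normalized cell
weights `w(x, y) = h(x, y) / MN`:

* **Classical Rényi entropy (CR)**:
  `CRα(DRi) = (1/(1−α)) · ln Σ_{(x,y)∈DRi} w(x,y)^α`.
* **Quantum Rényi entropy (QR)**: each cell is encoded FRQI-style as a
  single-qubit state `cos θ|0⟩ + sin θ|1⟩` with `θ = (π/2)·w(x,y)`; a
  rectangle's amplitude sums `C = Σ cos θ`, `S = Σ sin θ` define the
  rank-one density operator `ρ = (C,S)(C,S)ᵀ`, and
  `QRα(DRi) = (1/(1−α)) · ln trace(ρ^α)`, evaluated through the spectral
  decomposition of the 2×2 `ρ` (its nonzero eigenvalue is `C² + S²`).

The fitness of `X` is the sum over the `k + 1` rectangles (order `α = 0.01`
by default), maximized by particle swarm optimization (PSO), differential
evolution (DE/rand/1/bin), or — at small scale — exhaustive search. The
optimal row thresholds `t*` then reconstruct the segmented image: pixels in
`[t(i−1)+1, ti]` are replaced by the rounded mean of their class. A
nine-metric suite (PSNR, SSIM, AMBE, CII, SD, edge density, REC, SF, CIR)
and a benchmarking harness with rank tables and Wilcoxon signed-rank tests
support method comparison.

## Worked example

```r
library(qrseg)

# a reproducible three-class test image: bands at 60/128/200, sigma = 8 noise
fx <- make_piecewise_image(fixture_spec(size = c(128L, 128L),
                                        class_means = c(60L, 128L, 200L),
                                        noise_sigma = 8, seed = 42))

res <- segment_image(fx$image, k = 2,
                     params = entropy_params(alpha = 0.01, mode = "quantum"),
                     config = optimizer_config(seed = 1), method = "pso")
res
#> <segmentation> PSO-QR, k = 2, alpha = 0.01, enhance = identity
#> <optimizer_result> PSO: k = 2, best fitness = 0.538943 after 162 iterations
#>   t* = (87, 172), v* = (87, 170)
```

The recovered row thresholds 87 and 172 fall between the true class means
(60 | 128 | 200), so the three noisy bands are classified correctly; the
fitness is the summed quantum Rényi entropy of the three diagonal
rectangles at the optimum, and 162 is the iteration count at which PSO's
stagnation rule fired. Quality of the reconstruction against the input:

```r
compute_metrics(res$enhanced, res$segmented)
#> # A tibble: 1 × 9
#>    psnr  ssim   ambe    cii    sd edge_density   rec    sf   cir
#>   <dbl> <dbl>  <dbl>  <dbl> <dbl>        <dbl> <dbl> <dbl> <dbl>
#> 1  30.0 0.539 0.0588 0.0759  57.4       0.0320 0.761  8.95 0.810
```

30 dB PSNR and AMBE ≈ 0.06 gray levels say the three-level rendering sits
close to the noisy original with its brightness preserved; SD grows because
class-mean flattening removes within-class noise while keeping the
between-class spread. `autoplot(res)` shows the segmented raster,
`tidy(res$optimizer)` the convergence trace, and `run_benchmark()` compares
PSO-CR / DE-CR / PSO-QR / DE-QR across images and `k` with rank tables and
Wilcoxon tests.

A thin command-line wrapper is installed at `inst/cli/qrseg.R`:

```sh
Rscript inst/cli/qrseg.R segment --input in.png --output out.png \
    --k 2 --entropy qr --optimizer pso --seed 5 --report report.json
```

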