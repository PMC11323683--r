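# sipod — spatial outlier detection via iterative thresholding

Outliers in spatially indexed regression data are doubly awkward: spatial
error dependence breaks the independence assumptions behind classical
residual diagnostics, and multiple outliers mask one another. `sipod`
detects mean-shift outliers and produces robust coefficient estimates
under the spatial error model (SEM), for analysts working with areal or
networked observations (epidemiology, regional science, environmental
monitoring).

## The model and method

The data model is an SEM with a sparse mean-shift vector marking the
outliers:

    y = Xβ + γ + ξ,   ξ = μWξ + ε,   ε ~ N(0, σ²I)

Observation *i* is an outlier iff γᵢ ≠ 0. For known or estimated μ, the
whitening transform ỹ = (I − μW)y, X̃ = (I − μW)X returns the problem to
an independent-error mean-shift regression, which is solved by iterating
a thresholding rule Θ (soft or hard) on working residuals with
leverage-adjusted per-observation thresholds λᵢ = λ√(1 − hᵢ):

    γ ← Θ( Hγ + (I − H)y ; λᵢ ),   H = X(XᵀX)⁻¹Xᵀ

The level λ is tuned by a modified BIC,
`BIC*(λ) = m log(RSS/m) + k(log m + 1)` with m = n − p and k = (#flagged)
+ 1, over a decreasing 100-point λ path with warm starts. When μ is
unknown it is estimated by robustified-likelihood scoring with a bounded
influence function ψ (Cauchy, Welsch, Insha or logistic). A simulation
module regenerates the benchmark conditions (equicorrelated uniform
design, leverage rows, a shift-8 contamination block, AR-decay weights on
a line graph, SEM noise), and an evaluation module computes the masking /
swamping / joint-detection / coefficient-MSE benchmark table.

## Worked example

```r
library(sipod)
d <- make_dataset(scenario(n = 200, p = 5, O = 10, seed = 42))
fit <- spatial_ipod(d$X, d$y, d$w, rule = "soft", mu = 0.7)
print(fit)
masking(fit$outlier_idx, d$truth)          # fraction of true outliers missed
swamping(fit$outlier_idx, d$truth, 200)    # fraction of clean points flagged
```

```
Spatial Theta-IPOD fit (soft rule)
  mu: 0.7000 (fixed)
  flagged outliers (transformed scale): 15 (1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 25, 147)
  selected lambda: 1.237, BIC*: -240.7752
  beta: 1.0046 1.0163 0.9798 1.0202 0.9964
masking: 0  swamping: 0.02631579
```

All ten planted outliers (units 1–10, a contiguous block with shift 8)
are flagged — masking 0 — and the coefficient estimate is within about
2% of the true β = (1,…,1) despite 5% contamination. Units 11–13 are
the block's right-hand neighbours: on the whitened scale a shift block
leaks signal of opposite sign into adjacent clean units, so flagging them
is a property of the transformed-scale definition, not noise; 25 and 147
are ordinary swamping (2.6% of the clean units, the modified BIC's normal
operating point). Estimating μ on the same data illustrates the
documented limitation with *adjacent* contamination:

```r
romle_fit(d$X, d$y, d$w, psi_kind = "cauchy")
```

```
SEM estimate (romle, psi = cauchy): mu = 0.9243, sigma = 0.4961, converged: TRUE
  beta: 1.0030 1.0066 0.9787 1.0284 0.9952
```

The shift block masquerades as extra spatial correlation and inflates
μ̂ from 0.7 to 0.92 (every bounded ψ family behaves this way); on clean
or scatter-contaminated data the same estimator recovers μ to within a
few hundredths. The vignette
(`vignettes/spatial-outlier-detection.Rmd`) develops the model, the
penalty construction, the BIC support cap, and this identifiability
limitation in detail.

A thin command-line wrapper is installed at `exec/sipod`
(`sipod detect|simulate|benchmark`), reading dense CSV or GeoDa GAL/GWT
weight files and writing per-observation CSV and JSON model reports.

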