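---
title: "Kinetic quantification of dNTPs from fluorescent progress curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic quantification of dNTPs from fluorescent progress curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dntpquant)
```

## The measurement problem

Polymerase-based fluorescent dNTP assays measure the limiting dNTP species
in a nucleotide extract by single-cycle primer elongation on a synthetic
template: each incorporation event lets the polymerase's 5'-3' exonuclease
cleave a quenched fluorophore off a hybridized probe, so fluorescence rises
as the limiting dNTP is consumed. The complication is that a thermostable
polymerase also hydrolyzes the probe without any dNTP incorporation: a
blank reaction (no specific dNTP at all) still produces a large, slow
fluorescence rise. A second complication is that components of a biological
extract slow both reactions unpredictably, so a fixed-time fluorescence
read-out against a water calibration fails — often producing negative
"amounts" for real samples.

Both problems dissolve under kinetic treatment. Every well's progress curve
is fitted with both a single- and a double-exponential model (written so
that amplitudes come out positive):

$$F(t) = F_0 - A\,e^{-k_{obs} t}
\qquad\text{and}\qquad
F(t) = F_0 - A_1 e^{-k_{1obs} t} - A_2 e^{-k_{2obs} t},$$

where the fast phase ($A_1$, $k_{1obs}$, typically $\sim 2.5\times10^{-3}$
s$^{-1}$) reflects specific dNTP incorporation and the slow phase ($A_2$,
$k_{2obs} \sim 10^{-4}$ s$^{-1}$) the background hydrolysis. This is
single-cycle primer elongation, not PCR, so quantification-cycle analysis
does not apply. The fast-phase **amplitude** $A_1$ is proportional to the
amount of the limiting dNTP and — crucially — insensitive to the kinetic
inhibition by the sample matrix, which scales the rate constants but not
the amplitudes. Quantification therefore proceeds by linear calibration of
$A_1$ against known amounts.

## Model selection

The models are nested (the single model is the double with $A_2 = 0$) and
over-fitting the blank with the double model produces two inseparable
phases. Each well is fitted with both models and the corrected Akaike
information criterion decides:

$$AIC = 2k + N\ln(RSS) + \begin{cases} 0 & N/k \ge 40\\
\frac{2k(k+1)}{N-k-1} & N/k < 40,\end{cases}$$

with $k = 3$ (single) or $5$ (double) parameters and $N$ data points.
Blanks select single; dNTP-containing wells select double. Ties — which in
practice only arise for numerically perfect fits — go to the model with
fewer parameters, and a numerically zero $RSS$ (below
$(10^{-8}\,\Delta F)^2$ per point, with $\Delta F$ the data range) is
treated as the perfect-fit sentinel for the same reason: comparing
logarithms of rounding noise is meaningless.

A double fit whose two rate constants agree within 1%, or whose amplitudes
sit on the zero bound, has not actually separated two phases; such
degenerate fits defer to the single model regardless of raw AICc.

## Fitting details

Fits are unweighted nonlinear least squares (Levenberg–Marquardt with box
bounds, via `minpack.lm`). Amplitudes are bounded below by 0 and rate
constants confined to $[10^{-7}, 1]$ s$^{-1}$, a window that generously
brackets both phases at any plausible temperature and polymerase. Starting
values are deterministic: $F_0 \leftarrow \max F$, total amplitude
$\leftarrow \max F - \min F$, the single-model rate from a log-linear
regression of $\ln(F_0 + \epsilon - F)$ on $t$, and the double model seeded
at the field-typical rates $(2\times10^{-3}, 10^{-4})$ s$^{-1}$ with a
30/70 amplitude split. If the deterministic start fails, up to 12
randomized restarts (log-uniform rates, random amplitude split) are tried;
persistent failure is *reported* as a non-converged well, never raised as
an error. Standard errors come from the local linearization at the optimum
(the usual nonlinear-regression covariance); they underestimate uncertainty
for strongly correlated parameters, which is one reason the error-based QC
checkpoint below exists. Phases are reported fast-first ($k_{1obs} >
k_{2obs}$), reordering the fitted pair if needed; the pre-reordering fast
amplitude is retained for the inverse-run checkpoint.

Fluorescence units are arbitrary and never rescaled on input — the
calibration absorbs any scale. Likewise the time origin: the first recorded
cycle is assigned $t = 0$, and any constant instrument offset is absorbed
by $F_0$ and the amplitudes without affecting $A_1$.

## Lag trimming

Some samples show a 100–200 s lag before the rise. Lag points are
eliminated before fitting: every candidate trim that removes at most
`max_lag_s` (default 240 s) of initial data is refitted, and the trim
minimizing a per-point AICc is kept, with time re-zeroed. Because trims
change $N$, this comparison uses the mean squared residual,
$\ln(RSS/N) + 2k/N\,(+\,\text{correction}/N)$ — the raw $N\ln(RSS)$ form is
only meaningful at fixed $N$ and would otherwise always favour shorter
data. Ties prefer the shortest trim, so clean curves are left untouched.
The trim search is this package's construction; the underlying assay
behaviour it addresses (lag elimination improves fit quality) is standard.

## QC checkpoints

Six per-well checkpoints mark unreliable wells, which are excluded from
calibration and quantification and surface in the report with one-line
explanations:

1. **Inseparable phases** — the single model won AICc on a well expected to
   contain the specific dNTP. Blanks are exempt (they are *expected*
   single-exponential).
2. **Amplitude error** — $se(A_1) > A_1$.
3. **Fast rate within slow range** — $|k_{1obs} - \overline{k_{2obs}}| \le
   m\cdot SD(k_{2obs})$ over the plate's converged double fits; the width
   $m$ defaults to 1 SD and is configurable, since "within the error range
   of the average" admits several formalizations.
4. **Slow phase too slow** — $k_{2obs} < 10^{-5}$ s$^{-1}$, strictly: a
   well at exactly $10^{-5}$ passes.
5. **Inverse run** — raw fitted $A_1 \le 0$. With the zero lower bound on
   amplitudes a decreasing curve pins the amplitude at 0 rather than going
   negative, so the checkpoint fires on the bound.
6. **Signal too small** — fitted total amplitude ($A_1 + A_2$) below half
   of the lowest calibration point's. The fitted total is used instead of
   the raw max−min for noise robustness.

Checkpoints whose plate context is missing (too few double fits, no usable
lowest calibration point) are skipped and recorded as not evaluated rather
than silently passed.

## Calibration, LOD/LOQ and normalization

The calibration is an ordinary least-squares line through (amount, $A_1$)
of the QC-passing calibration wells; by default all passing points are
used, with an optional user-restricted range and a refinement loop for
excluding outlier wells. Low-concentration wells where the double fit
failed are recorded as points under the detection limit.

LOD is estimated two ways and the larger is reported: (A) the lowest
calibration amount whose replicates all fitted and passed QC, and (B)
$3\,SD(A_1^{low})/\text{slope}$ — the amplitude-axis "offset + 3 SD"
criterion re-expressed on the amount axis, where subtracting the intercept
cancels the offset. LOQ is the same with $5\,SD$; $LOD \le LOQ$ always.
Taking the maximum implements the rule that a mathematical limit below the
lowest resolvable calibration point is replaced by that point.

Unknowns are quantified by inverse prediction, $\hat{c} = (A_1 -
\text{intercept})/\text{slope}$, flagged when below LOD/LOQ or above the
fitted range, and normalized to $10^6$ cells (human samples) or $10^8$ CFU
(bacterial samples) through the dilution factor and the extract/assayed
volume ratio. Accuracy statistics use the mean measured/nominal ratio
(inverse prediction based), CVs use the sample SD ($n-1$), and
standard-addition recovery is the difference quotient
$100(\text{spiked} - \text{unspiked})/\text{added}$ — choices the package
documents because the conventional definitions vary between labs.

## Amplitude competition and the quadratic binding model

The fast and slow phases compete for the same
polymerase:template:primer:probe (ETPP) complex, so the *relative* fast
amplitude $relA_1 = A_1/(A_1+A_2)$ follows a 1:1 stoichiometric
(tight-binding) curve in the total added dNTP $L_T$:

$$relA_1(L_T) = F_0 + A_{quad}\,
\frac{(E_T + L_T + K_{app}) - \sqrt{(E_T + L_T + K_{app})^2 - 4E_T L_T}}
{2E_T}.$$

Only the minus root is physical — it gives $F_0$ at $L_T = 0$ and
saturates at $F_0 + A_{quad}$; the plus root diverges and is rejected. In
this parameterization the intercept $F_0$ and the saturating step
$A_{quad}$ play the roles sometimes labelled $S$ and $A$ in figure legends;
the identification is confirmed by the fact that the fast- and slow-phase
fits mirror each other ($A_{quad}$ of equal magnitude, opposite sign, same
$E_T$ and $K_{app}$) and sum to 1 at all $L_T$. $E_T$ is fitted freely by
default — its published uncertainty suggests the original analysis did the
same — with an option to fix it at the nominal complex amount.

For a dTTP characterization the saturating $relA_1$ is about 0.71: roughly
30% of the ETPP complex is consumed by background hydrolysis before the
specific dNTP can be incorporated, which is exactly why amplitude-based
calibration must use $A_1$ and not the total signal.

```{r binding}
dttp <- list(A_quad = 0.660, F0 = 0.054, E_T = 8.345, K_app = 0.741)
round(eval_quadratic_binding(dttp, 1e4), 3)
```

## The synthetic plate generator

Because instrument exports are not redistributable, every pipeline stage is
exercised against synthetic plates with complete ground truth. The
generator's defaults emulate a dGTP-style calibration run: blank kinetics
$A \approx 28\,900$, $k \approx 2\times10^{-4}$ s$^{-1}$, plateau
$\approx 36\,000$ fluorescence units; dNTP wells with $k_1 = 2.5\times
10^{-3}$, $k_2 = 1.1\times10^{-4}$ s$^{-1}$ and total amplitude
$\approx 29\,900$; a calibration slope of $\sim 1000$ units/pmol; the
split-time schedule (100 cycles of 13 s, then 200 of 80 s — short early
cycles resolve the fast phase, long late ones the slow phase); additive
Gaussian read noise with SD 2% of the total amplitude; and an optional
per-well matrix-inhibition factor in $(0,1]$ that scales both rate
constants while leaving amplitudes untouched. Lag is modelled as a flat
hold at $F(0)$ — the simplest shape consistent with the observed 100–200 s
lags. All randomness derives from the spec's single seed.

```{r plate}
samples <- data.frame(sample_id = c("s1", "s2"), true_pmol = c(2, 5),
                      extract_volume_ul = 50, assayed_volume_ul = 10,
                      cells_extracted = 5e5, basis = "per_1e6_cells")
pl <- synth_plate(plate_spec(samples = samples, noise_frac = 0.01, seed = 1))
an <- analyze_plate(pl$curves, pl$layout, fit_config(max_lag_s = 0))
an
```

What passing tests on these plates do and do not show: they demonstrate
that the decomposition, selection, QC and calibration machinery recovers
known ground truth under realistic noise, matrix slowing and lag — but the
generator draws independent Gaussian read noise and ideal exponential
kinetics. Real curves carry correlated drift, occasional non-exponential
onsets, pipetting variation in the calibration series and batch-dependent
oligonucleotide quality; performance on real plates is bounded by those
effects, which is precisely what the QC checkpoints are for.

## Problem sizes and numerical choices

The test and acceptance workloads use single 96-well plates (300-point
split-time curves), a 72-case noiseless parameter grid spanning rates
$5\times10^{-5}$–$5\times10^{-3}$ s$^{-1}$, amplitudes 500–30 000 and
plateaus 5 000–40 000, and 30-sample quantification plates at 2% noise —
sizes chosen to match one real plate's worth of data. Convergence
tolerances are $10^{-10}$ (relative, on both sum of squares and
parameters); rate bounds $[10^{-7}, 1]$ s$^{-1}$; the degenerate-rate
margin 1%; and trims never reduce a curve below 8 points, the container's
own minimum. Known limitations: standard errors are linearization-based;
the double model is weakly identified when the acquisition window is much
shorter than $1/k_{2obs}$ (use split-time schedules); and dUTP
quantification is out of scope — the kinetic difference between dUTP and
dTTP incorporation makes amplitude-based dUTP readout unreliable, so the
package stops at annotating dUTP plates.
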