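---
title: "Proteome dynamics from heavy-water labeling: model, tunables, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome dynamics from heavy-water labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proturn)
```

## The measurement model

Heavy-water labeling turns protein synthesis into a mass-spectrometric
observable. After a bolus of ²H₂O plus maintained enriched drinking
water, body water holds a steady deuterium enrichment $p_w$ (~5% in the
default protocol). Free amino acids equilibrate with body water at a
subset of their carbon-bound hydrogens; a protein molecule synthesized
*after* label onset therefore carries extra deuterium, while pre-existing
molecules do not. At the peptide level this mixes two mass-isotopomer
patterns:

* the **natural** pattern of the peptide's elemental composition, and
* the **labeled** pattern, the natural pattern convolved with a binomial
  $\mathrm{Bin}(N_{EH}, p_w)$ distribution of incorporated deuteriums over
  the peptide's $N_{EH}$ exchangeable hydrogen sites.

With $f(t) = 1 - e^{-kt}$ the fraction of the pool synthesized since
label onset, the observed isotopomer proportions are
$(1-f)\,\mathbf{m}_{nat} + f\,\mathbf{m}_{lab}$, and the total labeling

$$I(t) = 1 - \frac{M_0(t)}{\sum_j M_j(t)}$$

rises exponentially from the natural baseline $I(0)$ to a plateau set by
$p_w$ and $N_{EH}$:

$$I(t) = I(0) + \bigl(I(plateau) - I(0)\bigr)\,(1 - e^{-kt}).$$

Because $I$ is a ratio, it is invariant to the peptide's absolute ion
count, which is why raw intensities can be used directly. Under metabolic
steady state (constant pool size) the fractional synthesis and catabolic
rates coincide and equal $k$; the half-life is $t_{1/2} = \ln 2 / k$.

Assumptions inherited from this model: a single precursor compartment at
constant enrichment (no label ramp-up or decay), no isotope-effect
correction on the per-site labeling probability (it equals $p_w$), and
first-order turnover of each protein.

## The isotopomer forward model

`natural_distribution()` convolves per-element isotopologue distributions
(one fixed published abundance set, see `natural_abundances()`) and keeps
the first `n_iso` nominal-mass isotopomers. The default `n_iso = 6`
(M+0…M+5) captures >99.9% of the pattern for tryptic-size peptides at
≤5% enrichment; the truncated mass is always reported in the
`truncation` attribute rather than silently renormalized. Truncated
convolution is exact for the retained coefficients, so truncation never
biases M₀…M₄, it only loses tail mass.

Exchangeable-hydrogen counts are per-residue literature-style averages
(Ala 4.00, Gly 2.06, Leu 0.60, …) shipped as a plain TSV
(`inst/extdata/residue_composition.tsv`) and overridable via
`residue_table(path)`. They are configuration, not a measured quantity:
the simulator and the QC plateau prediction share one table so plateau
predictions are reproducible. Because the table holds residue averages,
$N_{EH}$ is generally non-integer; the incorporation distribution is the
linear interpolation of the binomials at the two bracketing integers —
deterministic and smooth in $N_{EH}$.

## What the simulator emulates — and what it does not

`generate_cohort()` states the experimental world the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| group sizes | 7 control, 6 HFD | "6–7 per group" cohorts; the assignment is a convention |
| sampling times | 0, 8, 24, 48, 96, 168 h | baseline + four draws + 7-day terminal sample |
| body-water plateau | 5% | observed steady state under 30 µL/g bolus + 8% drinking water |
| peptides/protein | 3–20 unique | quantifiable-peptide range per protein |
| peptide length | 8–25 residues | typical tryptic peptides |
| total intensity | log-uniform 10⁶–10⁸ counts | the quantifiability window itself |
| intensity noise | 3% CV, lognormal per isotopomer | realistic MS1 quantification error |
| proportion jitter | 1% lognormal, renormalized | small pattern distortion beyond intensity noise |
| animal-level k CV | 8% lognormal | gives group SDs resembling the catalog's |

Protein half-lives come from the packaged 34-protein HDL catalog
(`hdl_halflife_catalog()`); the diet effect acts on $k$ only, not on the
plateau, since body-water enrichment is similar across animals. Animal
draws are mean-preserving in $k$ (lognormal with $\mu$ shifted by
$-\sigma^2/2$), so ledger group means track the catalog half-lives up to
Jensen's inequality (<1% at 8% CV). All randomness flows from one
mandatory seed; output is bit-reproducible.

One deliberate numerical choice: the simulator mixes the *renormalized*
truncated natural and labeled patterns. Mixing unnormalized truncated
vectors would make $I(t)$ a ratio of two affine functions of $f$ — close
to, but not exactly, the exponential-rise model (the labeled pattern
loses more tail mass than the natural one). Renormalizing restores the
exact identity the fitter assumes, and since $I$ is scale-invariant it
changes no individual pattern's labeling value. Consequence: a green
recovery test establishes estimator correctness *under the stated model*,
not robustness to truncation-model mismatch, chromatographic
interference, retention-time drift, or precursor ramp-up — none of which
are simulated. The exponential equilibration mode of
`labeling_protocol()` exists for sensitivity checks of the constant-
precursor assumption.

## Fitting: initialization, bounds, convergence, outliers

`fit_exponential()` estimates $(k, I(0), I(plateau))$ by nonlinear least
squares. Initialization is deterministic: $I(0)$ from the measured
baseline, plateau from the last point, $k$ from the through-origin slope
of $-\log(1-\hat I)$ on the plateau-normalized series. The port
algorithm does the main descent; a damped Gauss–Newton polish with the
analytic Jacobian then drives the solution to machine precision, because
port's default stopping rule leaves ~5×10⁻⁴ relative error on noiseless
data. Convergence is declared from first-order stationarity of the final
parameters, not from an optimizer exit code — port errors out on
zero-residual data and L-BFGS-B can abort on very flat SSE surfaces while
already at the optimum.

Bounds: $k \in [10^{-5}, 2]\ \mathrm{h}^{-1}$ (physical range for a
7-day protocol). The plateau bound deserves a note: the total labeling of
a tryptic-size peptide starts from a *large* natural baseline (~0.4–0.6,
most peptides have >20 carbons) and plateaus at ~0.6–0.9 under 5% body
water, so the plateau's upper bound is 0.995, just below the
mathematical ceiling of 1. A bound at 0.5 would be appropriate only for
a baseline-subtracted labeling scale, which Eq. 1 is not. The plateau is
a free parameter by default (`fix_plateau` pins it, e.g. to
`asymptotic_labeling()`, for sensitivity analysis); the theoretical
plateau is carried in the simulator's peptide table as a QC comparison.

Outlier handling replaces an interactive, software-specific cleaning step
with a reproducible rule: externally studentized residuals (linearized
hat matrix from the analytic Jacobian), threshold 3.0, at most one
removal per series, refit after removal. Two guards: a removal that
would leave fewer than 4 points is blocked and the series flagged; and
the $t=0$ baseline is never removed, only flagged. The latter matters
because with 6 points and 3 parameters the studentized residuals have 2
degrees of freedom and exceed 3 in roughly 10% of *clean* points — an
unavoidable property of such short series — and removing the baseline
would invalidate the refit, which anchors $I(0)$ at the measured
pre-label sample.

Peptide fits aggregate to protein turnover per animal as the unweighted
mean of converged peptide $k$ (≥3 required); the protein half-life is
$\ln 2 / \bar k$, so $t_{1/2} \cdot \bar k = \ln 2$ holds exactly by
construction. Inverse-variance weighting is deliberately not the default:
the averaging in the emulated workflow is unweighted.

## Cohort statistics

Per protein, the two groups are compared with a two-tailed Student
t-test on per-animal rate constants (pooled variance; Welch optional).
No multiple-testing correction is applied by default, matching the
emulated analysis; `p_adjust = "BH"` is available. Cohort-level outputs:

* group mean half-lives; in per-animal mode the group contrast tests
  per-animal mean half-lives (n = animals), in summary-statistic mode a
  paired t-test across proteins;
* percent mean half-life reduction $100(1 - \bar t_{HFD}/\bar t_{ctrl})$;
* percent of proteins significant-and-reduced;
* the regression of treated on control half-lives **through the origin**
  ($\hat\beta = \sum xy / \sum x^2$) with the Pearson $r^2$ of the pairs.
  The through-origin slope is the right scatter-plot summary of a
  proportional change (slope 0.83 ⇔ ~17% reduction); the centered OLS
  slope is reported alongside for transparency.

Summary-statistic mode tests printed catalog rows (means ± SD) at
assumed group sizes. Since only "6–7 per group" is known,
`reproduce_catalog()` reports the significant fraction under all four
(n₁, n₂) combinations as a QC attribute. Three catalog rows cannot be
reconciled with their printed significance marks from summary statistics
alone (complement factor B significant-but-unmarked; serotransferrin and
prothrombin marked-but-not-significant); the package reports recomputed
flags next to the printed ones and never overwrites either — the original
tests presumably used per-animal values that summary rows cannot recover.

## Degenerate inputs and numerical conventions

* All-zero isotopomer vectors are rejected; all-zero time points are
  dropped and flagged, never imputed.
* Series without a measured baseline, spanning <48 h, or with <4 points
  are rejected with named reasons; every input series lands in exactly
  one of the fits table or the exclusion report.
* The intensity window applies to the summed isotopomer intensity per
  time point; a series needs ≥5 in-window points *including the
  baseline*.
* Time is hours end-to-end (a `time_d` column is converted on read);
  fitting is invariant to time-unit rescaling up to the documented
  1e-9 tolerance on parameters.
* Ties in outlier candidates resolve to the largest residual first.

## Known limitations

* The forward model ignores fine isotope structure, charge states and
  post-translational modifications; compositions cover C/H/N/O/S only.
* The precursor model has no label decay (washout designs are out of
  scope) and the instantaneous mode idealizes the first hours of
  labeling.
* Exchangeable-hydrogen counts are residue-level averages; peptides with
  unusual sequence context will deviate from the predicted plateau — one
  reason the plateau is fitted freely rather than fixed.
* Summary-statistic t-tests cannot reproduce per-animal pairing or
  heteroscedasticity in the original data, as the three discrepant
  catalog rows demonstrate.
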