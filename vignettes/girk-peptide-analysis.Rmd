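---
title: "Methods: kinetic and pharmacological analysis of peptide-modulated GIRK recordings"
author: "girktools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic and pharmacological analysis of peptide-modulated GIRK recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girktools)
```

## The experimental situation being modeled

G protein-coupled inward-rectifier potassium (GIRK) channels expressed in
*Xenopus* oocytes are recorded under two-electrode voltage clamp (TEVC) at a
holding potential of −90 mV. Switching the bath from a low-potassium
solution (ND96, 2 mM K⁺) to a high-potassium solution (HK, 96 mM K⁺) moves
the K⁺ reversal potential from about −98 mV to near 0 mV, so a large basal
inward K⁺ current develops at the negative holding potential. Bath
application of an activating peptide ligand reversibly enhances that
current; washing the ligand out restores the basal level. Separate 1-s
voltage ramps (−150 to +60 mV) taken before and during application
characterize the current–voltage relation, and a concentration series
yields a dose–response curve.

The package implements every stage of this analysis — and a synthetic-data
generator that produces such recordings with known ground truth, so each
stage can be verified quantitatively without any recordings on disk.

## Binding model

Ligand binding is a single-site reversible bimolecular reaction,
C + L ⇌ C:L, with second-order association rate constant α (µM⁻¹ s⁻¹) and
first-order dissociation rate constant β (s⁻¹). Occupancy `p(t)` obeys

dp/dt = α·L(t)·(1 − p) − β·p.

For a concentration step to L the approach to equilibrium is
mono-exponential with observed rate α·L + β; the apparent rates are
`k_on = α·L` and `k_off = β`, the wash-in and wash-out time constants are
`tau_on = 1/(k_on + k_off)` and `tau_off = 1/k_off`, and the affinity is
`kd = β/α`. The response (fractional current increase) is assumed linear
in occupancy — current is scaled by `1 + efficacy·p` — which makes the
equilibrium dose–response a Hill curve with coefficient 1 and EC50 equal
to kd. `derive_rate_constants()` inverts these relations exactly:
β from `tau_off`, `k_on = 1/tau_on − k_off` (requiring `tau_on < tau_off`;
equality means no detectable association), α = `k_on`/L, kd = β/α.

Because the fitted `tau_on` enters through a difference of reciprocals,
α is the least robust of the derived quantities; the reporting convention
is 3 significant figures throughout.

## What the generator emulates — and what it does not

`simulate_application_trace()` produces a trace in four steps:

1. **Solution exchange.** The commanded ligand concentration and external
   K⁺ follow the epoch protocol through a first-order filter with time
   constant `exchange_tau_s` (default 2 s, a typical gravity-perfusion
   chamber; 0 disables). Initial conditions equal the first epoch's
   targets, i.e. the recording starts in an equilibrated bath.
2. **Occupancy.** The binding ODE is advanced with the exact per-sample
   exponential update (the analytic solution for a constant concentration
   applied over each sampling interval), so with instantaneous exchange
   the noiseless output equals the closed form to machine precision.
   Occupancy starts at 0 — no ligand is pre-bound.
3. **Current.** I = g(V)·(V − E_K)·(1 + efficacy·p), with E_K from the
   Nernst equation and a Boltzmann chord-conductance curve
   g(V) = g_max / (1 + exp((V − V½)/k)), defaults V½ = −10 mV, k = 12 mV.
   This rectification form is *phenomenological*: it reproduces the
   qualitative shape of a strongly inward-rectifying I–V curve but is not
   a mechanistic Mg²⁺/polyamine block model, and no GHK flux correction
   is applied.
4. **Noise.** Gaussian white noise, default SD 0.005 µA, added under a
   user-supplied seed (`withr::with_seed`, so the ambient RNG is never
   disturbed and identical seeds give bit-identical traces).

Defaults were fixed once, before any analysis, at values a TEVC
practitioner would call realistic: sampling at 1 kHz (analysis-grade
recovery works equally at 5–10 Hz because the kinetics are in the tens of
seconds, and the bundled analysis scripts use 10 Hz to keep files small);
g_max = 10 µS giving ~0.9 µA of basal inward current at −90 mV in HK —
absolute basal amplitudes are not reported for the real system, so this
scale is arbitrary and flagged as such; temperature 295.15 K (room
temperature); α = 7.82×10⁻⁵ µM⁻¹ s⁻¹ and β = 6.33×10⁻³ s⁻¹, the
reference rate constants of the peptide–GIRK interaction (kd = 80.9 µM);
and efficacy = 1.99, chosen so that 48 µM (equilibrium occupancy
48/(48 + 80.9) ≈ 0.372) produces the ~74% current enhancement reported
for that system (0.741/0.372 ≈ 1.99).

What passing tests on these data do **not** show about real recordings:
there is no rundown or drift, no endogenous oocyte conductances, no
series-resistance or leak artifacts, the noise is white rather than
1/f-plus-line, and gating of the Kv control channel is a one-exponential
stand-in (only peak block is analyzed downstream). Parameter-recovery
results should be read as "the analysis chain is self-consistent and
unbiased under its own assumptions", not as an error bound for bench data.

## Fitting choices

`fit_single_exponential()` fits
`y = offset + amplitude·(1 − e^(−(t−t0)/tau))` (rise) or
`offset + amplitude·e^(−(t−t0)/tau)` (decay) by Levenberg–Marquardt
(`minpack.lm::nlsLM`). `t0` is fixed at the window start: the application
onset is protocol-driven and known from the epoch table, so freeing it
would only dilute precision. Initialization uses decile means (offset from
the first or last tenth of the window, amplitude from their difference)
and `tau = window/5`; `tau` is bounded in [sampling interval, 100×window].
A flat segment returns amplitude ≈ 0 with a `"degenerate amplitude"` note
rather than an error; an optimizer failure returns `converged = FALSE`
with the diagnostic message.

`fit_hill()` fits `response = 1 + Emax·Lⁿ/(Lⁿ + EC50ⁿ)` in two stages: a
double-reciprocal linearization seeds an `n = 1` fit, which seeds the full
three-parameter fit. Bounds — n ∈ [0.2, 5],
EC50 ∈ [min dose/100, max dose×100], Emax ∈ [0, 100] — keep the
under-determined four-point design from diverging silently; flat response
sets return a `degenerate` flag and no parameters. With fewer than three
distinct concentrations n is fixed at 1.

Plateau responses (`build_dose_response()`) are means over the last 20%
of each epoch (configurable), which skips the exchange transient; the
response is the ratio of current magnitudes |I_ligand|/|I_basal|, with
the basal epoch being the zero-ligand epoch immediately preceding the
application.

Group comparisons use the parametric unpaired t-test with Welch's
correction (`welch_t_test()`, delegating to `stats::t.test` with
`var.equal = FALSE`), two-tailed, with significance at p < 0.05 — the
convention of the experimental design this mirrors.

## I–V analysis conventions

* Reversal potential: linear interpolation between the samples bracketing
  the zero crossing; with multiple crossings (noise near reversal) the one
  nearest 0 mV is chosen, since the HK condition predicts ~0 mV.
* Chord conductance: g = I/(V − E_rev), reported in µS with the explicit
  µA/mV → µS conversion (1 µA/mV = 1000 µS); points within 1 mV of the
  reversal are masked `NA`, never infinite.
* Rectification ratio: both curves are interpolated piecewise-linearly
  onto a common 1 mV grid (no smoothing — transparency over cosmetics) and
  the ratio is oriented **basal over ligand**, matching the convention of
  the experimental figure it mirrors, so a uniform activator gives a flat
  curve below 1. The window is −140 to −30 mV, the inward limb; outward
  currents are excluded because the ratio becomes ill-conditioned around
  the reversal. A ligand-curve zero crossing inside the window raises a
  division-guard error. When several replicate pairs are available the
  per-curve ratio is computed first and summarized pointwise.

## Peptide-identity module

Masses use the standard residue monoisotopic/average tables embedded in
the package (no network); each disulfide bridge subtracts two hydrogens.
`reduce_alkylate()` models the standard preparation: bridges opened,
cysteines carbamidomethylated (+57.02146 Da); the constructor refuses a
cysteine fixed modification combined with `n_disulfides > 0`, since a
modified cysteine cannot be bridged. Tryptic digestion cleaves after K/R
except before P (Keil rule) with up to two missed cleavages.

Fragment ladders follow the MALDI-ISD/HCD conventions: `c = b + NH₃`, and
z ions are reported as the z+1 radical (z-dot) standard for ISD spectra
(classical z available via `zdot = FALSE`). A backbone cut that could
sever a disulfide-bonded cysteine pair — cysteines on both sides of the
cut in an oxidized peptide — yields a fragment of ill-defined mass; such
ions are emitted with a `crosslink_ambiguous` flag and `NA` m/z rather
than a guessed value. This is deliberately conservative: without the
bridge topology, any cut between the first and last cysteine is treated
as ambiguous, which matches the practical observation that ISD ladders of
native Kunitz peptides are readable mainly outside the disulfide-locked
core. Peak matching is greedy nearest-neighbour within 10 ppm by default
(Orbitrap-class accuracy), each observed peak used at most once; an
absolute 1 Da tolerance suits linear-mode MALDI data. Sequence coverage
counts backbone cleavage sites evidenced by at least one matched ion from
either terminus.

The bundled FASTA (`inst/extdata/synthetic_kunitz59.fasta`) is a
**synthetic** 59-residue Kunitz-like stand-in (6 cysteines, 3 bridges)
constructed for this package so that the identity workflow runs offline
at the full problem size; it is not a natural sequence, and its computed
masses are validated against an independent proteomics mass calculator,
not against any published value. `analysis/00_fetch_reference.R` can
replace it with the real reference accession when a network is available.

## Problem sizes and numerical tolerances

The test suite and analysis scripts simulate at 5–10 Hz with epochs of
8–15 wash-in/wash-out time constants — long enough that equilibrium
plateaus are converged to < 10⁻⁵ relative, small enough that the whole
suite runs in well under a minute. Key tolerances: noiseless occupancy
matches the closed form to 10⁻⁹ absolute; noiseless parameter recovery to
0.1%; noisy recovery (default noise, 20 seeded replicates) to 10%
median; EC50 recovery from noisy replicated dose–response data to 15%
median; trace I/O round-trips with sampling uniformity verified to 1 ns.

## Known limitations

* Single-site, single-exponential kinetics only; no multi-exponential or
  global fits across concentrations, and no cooperative binding schemes.
* The rectification curve is descriptive; fitted chord conductances
  inherit whatever physics the input I–V actually contains.
* Disulfide-ambiguous fragments are flagged, not mass-assigned; ISD
  coverage of oxidized peptides is therefore conservative.
* The Welch test is the only inferential procedure; no multiple-testing
  correction is offered (the mirrored design has a single planned
  comparison).

```{r example, eval = FALSE}
# a complete kinetic analysis in six lines
occ <- occupancy_model()            # alpha, beta, efficacy defaults
chan <- channel_model()
prot <- application_protocol(c(60, 800, 1300), rep("HK", 3), c(0, 48, 0))
tr <- simulate_application_trace(prot, occ, chan, sample_rate_hz = 10,
                                 seed = 1)
on <- fit_single_exponential(tr, c(60, 860), "rise")
off <- fit_single_exponential(tr, c(860, 2160), "decay")
derive_rate_constants(on$tau, off$tau, ligand_uM = 48)
```
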