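---
title: "Methods: motif features, flanking charge and binding affinity of PCNA ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif features, flanking charge and binding affinity of PCNA ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipflank)
```

## Scope and model

PCNA (proliferating cell nuclear antigen) is a homotrimeric DNA sliding
clamp whose three identical pockets bind short linear motifs (SLiMs) in a
large set of ligands: the canonical PIP-box `QxxΨxxϑϑ` (Ψ aliphatic
L/M/I/V, ϑ aromatic), the PIP-degron (a PIP-box with a basic residue at
motif coordinate +4, often with TD at positions 5–6), and the APIM with
the 5-residue consensus `[K/R][F/Y/W][L/I/V/A][L/I/V/A][K/R]`. This
package implements the quantitative pipeline used to ask which sequence
features of such motifs actually track binding affinity: motif-coordinate
assignment and canonicality classification, degeneracy statistics and a
sequence logo over a curated motif set, pH-dependent net charge per
residue (NCPR) of motif-flanking windows, NMR secondary-chemical-shift
helicity, fitting of SPR and ITC binding data, and regressions of those
features against `ln(KD)`.

## Motif coordinates and classification

The conserved Gln is position 1 and the two aromatics positions 7 and 8;
residues N-terminal of position 1 carry negative coordinates, residues
C-terminal of 8 are `+1, +2, ...`, and position 0 does not exist (the
axis matches the field's convention). The APIM core aligns structurally
to positions `6 … +2`; remaining context residues are numbered
contiguously outwards, so the APIM peptide `MDRWLVKW` with core `RWLVK`
maps M and D to positions 4 and 5 by back-extension. Spans always come
from curation, never from pattern scanning: many confirmed motifs are so
degenerate (e.g. Srs2 `ASSQMDIF` with a single canonical residue) that
re-detection would be ambiguous.

Classification is flag-based: `has_Q1`, `has_hydrophobic4` (L/M/I/V),
`has_aromatic7/8`, the degron's basic +4 and TD(5,6), and the APIM
consensus. The aromatic test at 7/8 accepts W in addition to Y/F, because
APIM-aligned entries legitimately place W at position 7 and excluding it
would misclassify them. An entry is an `apim` when the consensus matches,
a `pip_degron` when all four PIP anchors plus the basic +4 are present, a
`pip_box` with the anchors alone, and otherwise `unknown`.

Set-level statistics count entries lacking Q1, lacking the aliphatic at
4, and lacking exactly one or both aromatics; percentages round half-up
to integers, the convention of the printed census they are compared
against. The logo reports residue frequencies per coordinate and
information content `log2(20) − H` in bits without a small-sample
correction — at the census size (83 motifs) the correction is a
fraction of a bit and the logo is descriptive, not inferential.

### The shipped census fixture is synthetic

The published curated list itself is distributed only as a typeset table
that is not machine-readable here. The fixture
`curated_motifs_synthetic.tsv` is therefore a *labelled synthetic
reconstruction*: it contains the nine motifs whose sequences appear in
prose (p21, FEN1, MSH6, the UNG2 variant, Spd1, the APIM peptide, Srs2,
CAF1 with its printed alignment gap, and the *S. solfataricus* DNA
ligase), plus 74 generated rows engineered so the census marginals equal
the published degeneracy statistics (28, 10, 36 and 8 of 83). Tests
against this fixture therefore verify the census *machinery* and its
rounding conventions, not an independent re-transcription of the
published table. The census denominator is all 83 motifs, designed
peptides included — the reconstruction is calibrated to the printed
percentages under that convention, and `motif_set_statistics()` takes
whatever subset the caller passes, so the excluding-designed-peptides
variant is one filter away. Alignment gaps (`-`) occupy a coordinate but count as lacking every
residue feature, and are excluded from logo columns.

## Net charge per residue

Charges are computed per residue in two modes. *Fractional* mode uses
Henderson–Hasselbalch titration at the stated pH: acids contribute
`−1/(1+10^(pKa−pH))`, bases `+1/(1+10^(pH−pKa))`, with the default pKa
set D 3.65, E 4.25, C 8.3, Y 10.1, H 6.0, K 10.5, R 12.5 and termini
8.0/3.55 — standard biochemistry values, overridable by name. *Integer*
mode assigns K/R = +1, D/E = −1 and leaves His neutral (switchable),
matching the behaviour of the common NCPR tools; at pH 7.4 the two modes
differ mainly by the His tail (≈ +0.04 per His). Both modes are exposed
because the published analysis pipeline delegates to such a tool without
stating the mode; integer mode is the default for figure parity, and the
variant ordering below is identical under both. A frozen cross-check
against an independent implementation (Biopython's `charge_at_pH`, under
its own pKa table) agrees within 0.02 NCPR for the whole variant panel.

NCPR windows are the curated motif span ± `flank_len` residues of the
parent sequence (flank counting ignores the motif coordinate axis),
truncated at chain ends with truncation flags; NCPR is the window net
charge divided by the *effective* window length. Free terminal-group
charges enter only when the window reaches an uncapped chain terminus —
the measured peptides are N-acetylated/C-amidated, so their termini are
silent. The flank-length profile (mean NCPR at flank 1–9) averages only
entries whose windows are complete on both sides, reporting undefined —
not zero — lengths with no complete entry. For the p21 variant peptides,
whole-peptide NCPR is the relevant quantity (the peptides *are* motif
plus flanks): +9/25 = 0.36 for p21^140–164^ down to −3/18 for the
charge-inverted D1.2.

## NMR helicity

Secondary chemical shifts are `Δδ(i) = δ_obs(i) − δ_coil(i)`; unassigned
residues carry no Δδ and are excluded from averages. The shipped
random-coil table carries generic coil values (Cα and C′) for disordered
peptides at 25 °C, pH 6.3, with simplified nearest-neighbour terms; a
neighbour identical to the central residue contributes nothing (its
effect is considered folded into the baseline), and chain termini take no
out-of-range term. The table is labelled synthetic: it is not a
transcription of any published coil library, and every measured helicity
in the analyses derives from printed mean secondary shifts rather than
from this table, which only anchors the synthetic round-trip tests.

Mean Cα secondary shift converts to helicity as
`max(0, mean_scs/3.2)·100`, capped at 100 — 100% helix corresponds to a
mean Cα secondary shift of 3.2 ppm, and negative means clamp to 0. The
averaging window is configurable; the motif window is the default, since
the quantity of interest is helicity *over the motif*. For comparison
against tabulated values, `helicity_table_value()` reproduces the mixed
printed precision with a single rule: report an integer when the raw
percentage lies within 0.1 of an integer, otherwise one decimal, rounding
half-up (9.0625 → 9, 0.9375 → 1, 6.25 → 6.3, 3.75 → 3.8). Simpler rules
(always one decimal, or integer above a fixed cut) fail at least one
tabulated value. The Spd1 data were recorded at 4 °C; no temperature
correction is applied, only noted.

## Binding models

**SPR steady state.** `Rss = KA·c·Rmax/(KA·c·n + 1)`. The fit is
nonlinear least squares in `log(KA)` (for conditioning) with `n` fixed:
KA, Rmax and n are not jointly identifiable from the equilibrium curve
alone. KD = 1/KA is reported with a delta-method standard error; a KD
outside `[c_min/100, 100·c_max]`, or non-convergence, flags the record
unreliable. The fit requires ≥ 4 concentrations spanning ≥ 4-fold.

**SPR single-cycle kinetics.** Five sequential injections of twofold
serial dilutions (90 s contact, 225 s dissociation, no regeneration).
Within each constant-concentration interval the 1:1 Langmuir ODE
`dR/dt = kon·c·(Rmax − R) − koff·R` has the closed form
`R(t) = Req + (R0 − Req)·e^(−(kon·c+koff)(t−t0))`, chained continuously
across intervals. The global fit estimates (kon, koff, Rmax) on log
scale; `koff` above 1 s⁻¹ is flagged as beyond reliable instrument
resolution, mirroring how weak binders' rates are treated. The model
assumes bulk-shift-free, mass-transport-free 1:1 binding.

**ITC (reverse titration).** The cell holds the peptide and the syringe
the PCNA trimer; with three identical pockets per trimer the site
concentration is `n × [trimer]`. Cell totals follow the exact stepwise
displaced-volume recursion (each injection multiplies cell species by
`1 − dV/V0` and adds `c_syr·dV/V0` of titrant) rather than the
exponential approximation, which makes small-injection behaviour
bit-reproducible; heat conservation under splitting an injection holds to
~`(dV/V0)²`. The bound complex solves the mass-action quadratic
`B² − B(P+S+Kd) + PS = 0`, evaluated in the subtraction-safe form
`2PS/(b + √(b²−4PS))` and verified against a bisection root-finder to
1e−10. Injection heat is `dH·V0·(B_i − B_{i−1}(1 − dV_i/V0))` plus a
constant dilution offset. The cell volume defaults to 200 µL (the
instrument class used; the exact volume is configurable). The dilution
baseline is the mean of the last 3 injections when saturation (≥ 95%
bound cell species at the final injection) is reached; otherwise the fit
with free `n` aborts recommending `fix_n`, the same remedy applied to
the unsaturated charge-inverted variants. First-injection discard is off
by default and available as a flag. `ΔG = R·T·ln(KD)` and
`−TΔS = ΔG − ΔH`, so `ΔG = ΔH + (−TΔS)` holds identically. The printed
record of the p21 energetics carries `−TΔS` with inconsistent sign in
one place; only +190 kJ/mol satisfies the identity with ΔH = −230 and
ΔG = −40 kJ/mol, and that value is used.

## Regressions

Features regress against `ln(KD)` with KD in molar — natural log, not
log10. Duplicate affinities per ligand are averaged arithmetically on
the KD scale by default (the simplest reading of "an average was used"),
with the geometric mean exposed. R² is invariant under exchanging
regressor and response and under affine rescaling, and the OLS solution
is tested against the closed-form normal equations to 1e−10; p-values
come from the two-sided F test of the slope and are only reported from
n ≥ 3.

## Disorder consensus

Disorder predictors are never executed here; per-residue score tracks
arrive as files (keeping the pipeline download-free and predictor
versions pinned by the user). Consensus is the per-residue mean across
predictors with an *inclusive* 0.5 threshold (a mean of exactly 0.5 is
disordered). Motif annotation averages the consensus over the motif span
only (the window is configurable), calls D at ≥ 0.5, and reports
`consistent = FALSE` when predictors disagree across the 0.5 line —
the published census' "no consistency between predictors" class. Tracks
with missing residues are rejected, not imputed.

## Synthetic generators and what passing tests mean

Every instrument input has a seeded generator with known truth:
steady-state series and single-cycle sensorgrams from the closed-form
models, ITC isotherms from the one-set-of-sites model with a constant
dilution offset, shift tables inverting the helicity scale
(`δ_obs = δ_coil + 3.2·f` on the helical span), and motif sets with the
fixed p21-like core `QTSMTDFY`, S/G flanks carrying exactly prescribed
integer charges, and `ln(KD) = a + b·NCPR + N(0, σ)`. Defaults for the
law are a = −13, b = −16, σ = 0.5, chosen once to span the observed
four-orders-of-magnitude affinity range across flank charges (KD ≈ 6 nM
at NCPR 0.36 to tens of µM at negative NCPR). Noise is Gaussian with sd
expressed relative to the signal scale (the maximum absolute model
value) — the simplest defensible choice, as no instrument noise model is
published. Identical parameters and seed give bit-identical output.

The generators emulate idealized instruments: no drift, spikes, bulk
refractive-index jumps, mass transport, or baseline curvature, and
Gaussian noise of uniform scale. Recovery tests therefore demonstrate
the *estimators'* correctness and conditioning at the published designs,
not robustness to real instrument artifacts.

Problem sizes used by the test-suite recovery studies, chosen as the
smallest giving stable medians: 100 seeded ITC isotherms (19 × 2 µL
injections) at the p21 design with 2% noise; 11 kinetic sensorgrams
(1 Hz, five injections) at kon 1.7×10⁶ M⁻¹s⁻¹ / koff 0.14 s⁻¹ with 2%
noise; 21 steady-state series at KD 3 µM with 1% noise; 25 motif sets of
n = 50 at σ = 0.5. Observed envelopes: median kinetic |KD error| < 5%,
steady-state < 10%, ITC < 15% with median n within 3 ± 0.2, and the
regression slope within 2 standard errors in ≥ 80% of replicates.

## Known limitations

The census fixture is a statistical reconstruction, not a transcription
(above). The coil reference is generic, so absolute synthetic shift
values are not library-accurate (secondary shifts, being differences,
are unaffected). Steady-state fitting cannot separate n from Rmax; n
must come from prior knowledge. The ITC model covers one set of
identical sites only — no sequential or multi-site models — and SPR
fitting has no surface-heterogeneity or mass-transport terms. Literature
meta-analysis tables (affinities measured under heterogeneous
conditions) are accepted as input but not shipped.
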