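---
title: "Designing and analysing duplexed-aptamer microarray libraries with acekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing duplexed-aptamer microarray libraries with acekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acekit)
```

## The system being modelled

A duplexed aptamer (DA) is a switch built from two strands: an aptamer
selected to bind a ligand, and a short aptamer-complementary element (ACE)
hybridized to a window of it. Ligand binding can release the aptamer by two
routes. Under *conformational selection* the ACE first dissociates
spontaneously (rate $k_{\mathrm{off}}$, h$^{-1}$) and the free aptamer then
binds ligand. Under *induced fit* the ligand is recognised by the intact
duplex and catalyses its disruption, adding a ligand-dependent rate
$k^*_{\mathrm{off}}$ on top of $k_{\mathrm{off}}$.

On a microarray, thousands of surface-tethered ACEs are hybridized with a
fluorescently labelled aptamer, and dissociation is followed as
fluorescence loss between imaging rounds. Because released aptamer is
diluted into a large volume, rehybridization is negligible and the decay is
effectively irreversible. Each sub-array of a slide is incubated under one
condition: left dry (*Calibration*), incubated with assay buffer
(*BufferOnly*, measuring $k_{\mathrm{off}}$), or incubated with buffer plus
ligand (measuring $k_{\mathrm{off}} + k^*_{\mathrm{off,[L]}}$).

`acekit` implements the complete desk side of this assay: library design
and naming, spot-table IO, spot QC, calibration, rate estimation,
dose-response fitting, landscape assembly, nearest-neighbor
thermodynamics — plus a simulator that generates whole synthetic slides
with known ground truth, so every stage of the pipeline is testable
without laboratory data.

## Library design and coordinates

An ACE is identified by the aptamer coordinate of its 5′-most duplexed
base, its length, and an optional single-mismatch coordinate. Coordinates
are 1-based on the consensus; bases of a 5′ extension are numbered
$\dots,-2,-1$ and **coordinate 0 does not exist**. All window arithmetic
skips zero, so a 15-mer starting at $-5$ ends at $+10$:

```{r}
apt <- atp_dna_construct()
d <- parse_name("5'_-5C:15", apt)
format_name(d, apt, anchor = "3p")
```

For an aptamer of length $L$ the number of perfect-match ACEs with lengths
between $X$ and $Y$ is
$[(Y-X+1)(2L+1) - Y^2 + (X-1)^2]/2$, and the number of single-mismatch
designs is $[Y(Y+1)(3L-2Y+2) - X(X-1)(3L-2X+4)]/6$; both closed forms are
property-tested against brute-force enumeration for all
$1 \le X \le Y \le L \le 40$.

Mismatched probes substitute A for a perfect-match probe base G, C or T,
and T for A, producing A–C, A–G, A–A and T–T mismatches against the
aptamer. This substitution has no fixed point on a pure-ACGT/ACGU
sequence; the `degenerate` flag required by the design contract is
implemented generically but can only be `TRUE` for exotic substitution
schemes. Probes are always synthesized DNA (RNA aptamers are complemented
with U→A), carry a 3′ T$_{25}$ spacer by default to lift the duplex off
the slide surface, and are laid out in a seeded random arrangement that is
replicated identically across all sub-arrays of a slide.

The bundled `atp_dna_construct()` is a partial reconstruction: the 27-nt
consensus is the classical ATP-binding DNA aptamer, but of its 5-base 5′
extension only $-5$(C) and $-2$(T) are pinned by published construct
names; the remaining extension bases are a synthetic choice and the object
is documented accordingly.

## Spot QC

Three rejection rules are evaluated on the post-hybridization green image
of each sub-array, and a spot rejected there is excluded from all rounds:

1. **Low signal** — spot signal $< 200$ RFU (strict). The table's median
   pixel statistic stands in for the pixel mean, since pixel-level data
   are not retained in spot tables; this is a documented divergence from
   an image-level definition.
2. **Morphology** — the spot's pixel coefficient of variation exceeds the
   sub-array mean CV by more than $3\times$ the sample (n−1) standard
   deviation. Scale-free by construction.
3. **Background** — the spot's local background exceeds the sub-array
   mean background by more than $3\times$ its standard deviation.

An ACE with fewer than 3 passing replicates in *any* sub-array is excluded
dataset-wide and propagates as a blank heat-map tile. All inequalities are
strict, exactly as the rules are stated.

## Calibration and rates

For each DA, the fluorescence loss on a condition sub-array is divided by
the loss of the same DA on the Calibration sub-array, putting the
Calibration condition at exactly 100% and cancelling handling losses
(drying, washing, photobleaching). The calibration transfer is per-DA, not
a global scalar — sub-array layouts are identical, so every DA has a
matched calibration partner.

Rates use a single-interval first-order model. With the per-DA calibration
loss fraction $\varphi$, the corrected survival is
$S = F_{\mathrm{post}} / (F_{\mathrm{hyb}}(1-\varphi))$ and
$k = -\ln(S)/\Delta t$ with $\Delta t = 1$ h. The first-order form is a
modelling choice: the assay reports rates from one interval, and the
simulator uses the same generative law, so noiseless recovery is exact by
construction (the standard simulation-based-calibration posture). Survival
values above 1 are clipped with a flag; negative induced-fit rates are
retained unfloored for fitting and floored only for display.

The induced-fit dose response is fitted per DA by bounded
Levenberg–Marquardt (via `minpack.lm`):

$$k^*_{\mathrm{off,[L]}} = k^*_{\mathrm{off,max}} \,
  [\mathrm{L}] / (K_{\mathrm{Fit}} + [\mathrm{L}])$$

with $k^*_{\max,0}$ = max observed $k^*$, $K_{\mathrm{Fit},0}$ = geometric
mean of the concentrations, bounds $k^*_{\max} \in [0, 10k^*_{\max,0}]$
and $K_{\mathrm{Fit}} \in [10^{-3}\min[\mathrm{L}],
10^{3}\max[\mathrm{L}]]$, and tight (1e−15) convergence tolerances.
Points are unweighted; non-convergence and all-zero responses are flagged,
never silent. The fit is invariant to concentration-unit rescaling.

### Standard errors

Replicate noise is multiplicative and common to both imaging rounds of a
spot, so rate uncertainty is estimated from the scatter of the *paired*
per-spot ratio $\log(F_{\mathrm{post},i}/F_{\mathrm{hyb},i})$, in which
spot effects cancel; for $k^* = k_{\mathrm{L}} - k_{\mathrm{B}}$ the
calibration ratio cancels as well. With only ~5 replicates a raw per-DA
variance has 4 degrees of freedom and produces heavy t-tails, so per-DA
variances are moderated toward the sub-array pooled variance (prior df
50) — log-ratio noise is close to homoscedastic within an image, and the
moderated z statistics are approximately normal. Multi-slide dilution
designs pool Calibration and BufferOnly signals per DA across slides by
averaging before rate computation.

## Landscapes

A landscape maps $(N, L[, MM])$ to a scalar and is rendered as matrices:
the 5′-anchored view (rows = 5′ start coordinate, columns = length), the
3′-anchored view (rows = $N_3$), and the *enantio* pair of both, in which
southwest–northeast diagonals of the 5′ view collect DAs sharing a 3′
start site. Mismatch maps put windows in rows and the mismatched
coordinate in columns; the extra leftmost `PM` column holds the
perfect-match $(L-1)$-mer sharing the window's 3′ end (the structural
analogue of a 5′-terminally mismatched $L$-mer — the anchoring is
configurable in the sense that the plain 5′/3′ maps carry the alternative
alignment). Forward linear maps average contributing ACE values per
aptamer base (all covering ACEs, or only ACEs mismatched at that base);
reverse maps average per-base scores over each ACE's window. Means always
skip missing values; a cell or base with no contributors is missing, never
zero.

## Thermodynamics

Duplex free energies use the unified DNA/DNA nearest-neighbor
enthalpy/entropy set with duplex-initiation terms, evaluated at the assay
temperature, with the standard entropic monovalent-salt correction (zero
at 1 M) and a square-root divalent-to-monovalent equivalence
($+120\sqrt{[\mathrm{Mg}^{2+}]_{\mathrm{mM}}}$ mM). RNA-containing
duplexes are deliberately modelled as DNA:DNA — the convention used for
these arrays so that salt effects can be handled uniformly — which
slightly depresses predicted stabilities for purine-rich RNA strands.

Two deliberate simplifications, both consistent with the module's claim of
rank-order (not absolute) fidelity and both exercised by hand-summed
oracles in the tests:

* single mismatches lose the two flanking perfect-match stacks and gain a
  fixed identity-specific penalty (A·A 0.61, A·C 1.33, A·G 0.14, T·T 0.45
  kcal/mol) instead of full mismatch nearest-neighbor tables;
* `self_dG()` searches exhaustively over perfectly paired hairpins (stem
  ≥ 3 bp, loop ≥ 3 nt, tabulated loop penalties with a
  Jacobson–Stockmayer extrapolation) and perfect ungapped self-dimers
  (stacks plus initiation, without the self-complementarity symmetry
  term), with 0 as the no-structure ceiling. It ranks self-structure
  propensity; it is not a partition-function folder.

## The simulator and what passing tests mean

`make_scenario()` fixes the study conditions: two slides of six sub-arrays
(one Calibration, one BufferOnly, four Ligand each), eight log-spaced
ligand dilutions from 0.124 µM to 10 mM, five replicate spots per ACE,
$\Delta t = 1$ h, spot-failure rates of 0.2%, and a calibration
handling-loss fraction of 0.15. Hybridization signals follow a
Langmuir-like occupancy in the nearest-neighbor duplex free energy
($F_{\max} = 5\times10^4$ RFU, midpoint −10 kcal/mol, slope 2 kcal/mol),
and replicate noise is 10% lognormal.

The `atp_dna_like` preset plants induced fit exactly on 7–12-mer designs
overlapping a ligand-contact site at consensus coordinates 4–12 (99 such
designs on the 32-nt construct), with $K_{\mathrm{Fit}} = 200$ µM and
$k^*_{\mathrm{off,max}}$ scaled from 0.3 to 1.0 h$^{-1}$ by overlap
fraction over a 0.05–0.25 h$^{-1}$ spontaneous baseline — i.e. ligand
increases dissociation 6- to 10-fold at saturation. Mismatched variants of
hot windows get a 1.5× boost (capped at 1.2 h$^{-1}$), mirroring the
observation that single mismatches can enhance induced fit.
`cocaine_like` keeps the heterogeneous, structure-dependent hybridization
and $k_{\mathrm{off}}$ landscape but has zero induced fit everywhere;
`flat_null` is fully uniform.

Two generator choices deserve emphasis:

* the decay law and dose-response law *match the analysis model*, so a
  zero-noise dataset is recovered exactly (observed: $k_{\mathrm{off}}$
  and $k^*$ to ~1e−16 h$^{-1}$, fitted parameters to ~1e−15 relative).
  Passing these tests validates the pipeline's algebra, not the adequacy
  of the first-order model for real surfaces;
* base pixel-CV jitter and backgrounds are drawn from bounded uniform
  distributions ($\pm\sqrt{3}\,\mathrm{sd}$ of their nominal spread), so a
  healthy spot can never cross a mean + 3 sd cutoff and planted failures
  are recoverable exactly. Real scanner noise has heavier tails; on real
  data the QC rules will reject a small fraction of genuinely healthy
  spots, as any 3-sigma rule does.

The simulator does not model spatial gradients, print-tip effects,
scanner saturation, Cy3 quenching by duplex structure, or inter-slide
batch effects beyond the shared handling-loss fraction — so agreement on
synthetic data says nothing about those failure modes.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use the 141-design
perfect-match 7–12-mer library (adding 252 mismatched 12-mers where
relevant), two slides, five replicates — about 17,000 spot records per
simulated dataset — and a counting property sweep to $L \le 40$. These
sizes exercise every code path while keeping the full suite around half a
minute; all statistics scale linearly in spots and designs, and a full
42k-feature slide simulates in well under a minute.

## Known limitations

* The exact transformation from fluorescence change to h$^{-1}$ used in
  published surface-DA work rests on a kinetic model not restated here;
  the single-interval first-order form is an assumption, validated only
  against the matching generative model.
* Nearest-neighbor values are not comparable in absolute terms to
  partition-function servers; only orderings are asserted.
* GPR-dialect reading is a best-effort column mapping, not a fidelity
  claim about any particular deposited dataset.
* Dose-response fits are unweighted; replicate-variance weighting would be
  a natural extension but the assay convention leaves it unspecified.
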