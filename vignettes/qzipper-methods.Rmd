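---
title: "Models and methods behind qzipper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qzipper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qzipper)
```

This vignette explains the models the package implements, the parameters
that matter, what the synthetic generator does and does not emulate, and the
design decisions taken where the underlying science leaves the
implementation genuinely open.

## The Q-zipper grammar

polyQ amyloid nucleates as a steric zipper: two antiparallel β-sheets whose
glutamine side chains fully extend and interdigitate, with the terminal
amides hydrogen-bonding the opposing backbone. Because successive side
chains alternate 180° along a β-strand, only every other residue of a
strand can face a given zipper interface. The grammar reduces this
structural picture to integer sequence statistics:

* **Unilateral contiguity** `max_unilateral`: the longest run of glutamines
  at positions $i, i+2, i+4, \dots$ (either parity). Counted as the number
  of Qs in the run, so 5 unilaterally contiguous Qs span 9 residues.
* **Bilateral contiguity** `max_bilateral`: the longest run of consecutive
  glutamines, which can populate both faces of a strand and therefore
  permits lamellar (multi-sheet) growth.
* **Intramolecular threading**: a feasibility search for `n_strands = 4`
  disjoint, ordered strand windows of `strand_len = 6` residues whose
  connecting loops have at least `min_loop = 4` residues, or
  `min_loop_gly = 3` when the loop is entirely glycine.

### Why two loop minimums

Two facts must hold simultaneously: pure polyQ first supports the
four-strand monomeric nucleus at 36 residues ($4 \times 6 + 3 \times 4$),
and a 33-residue design of four Q6 tracts joined by GGG loops is competent.
Both are satisfied by a generic loop minimum of four residues that relaxes
to three for all-glycine loops — glycine's lack of a side chain permits the
tighter turn. A stated reading ambiguity: the nucleating pattern can be
written (QXQXQX$_{\ge 3}$)₄, where X$_{\ge 3}$ could mean either "three or
more X per loop" or a per-strand-gap count; we encode loops ≥ 3 (glycine) /
≥ 4 (generic) and note the alternative.

### The two-route competence rule

De novo competence requires both a nucleus (threading) and the ability of
that nucleus to propagate. The package distinguishes the two growth
geometries:

* **Unilateral route**: strand windows need one complete glutamine face
  (three alternating Qs in a window of six); propagation is axial and
  requires `max_unilateral >= 5`.
* **Bilateral route**: strand windows must be entirely glutamine;
  short-strand zippers propagate laterally, engaging the contralateral face
  of each strand, and require `max_bilateral >= 6`.

The distinction is forced by the zero-slack minimal design: its four Q6
tracts each provide one nucleating face and one growth face, so a single
Q→N substitution — although it leaves one parity track of the strand
intact — removes the lateral growth surface and abolishes competence. A
rule demanding only one intact face per strand cannot reproduce this
knockout; the two-route rule reproduces the entire competence panel (the
odd–even interruption series, the interrupter-identity series, the
length-variant series, double insertions, and the knockout).

### The asparagine-predominant series

Repeats of the form N$^q$Q with $q \ge 2$ have isolated glutamines (no
contiguity) and are never de novo competent, while remaining
template-competent under the Q+N composition heuristic (see below). The
$q = 1$ member is the strict alternation (NQ)$_{30}$, which carries the
identical every-other-position pattern as (QN)$_{30}$ — the two differ only
by a one-residue frame shift. A sequence grammar cannot, and in our view
should not, assign them different calls; the package classifies both
competent, and the test suite asserts this frame-shift consistency
explicitly. Reports of asymmetric behaviour between such constructs would
have to originate outside the sequence pattern itself.

### Template competence

Cytosols carrying a pre-existing Q/N-rich amyloid conformer cross-seed
compositionally similar sequences far more permissively than de novo
nucleation allows. No formal sequence rule for this route is established;
the package uses a stated heuristic — de novo competence, or a Q+N
composition fraction ≥ `qn_threshold` (default 0.5) — and reports it in a
separate column so it is never conflated with the grammar call. Borderline
cases (four unilaterally contiguous glutamines interrupted by the
permissive serine) are flagged in a `note` column; the ordinal
`disruption_rank()` (S < A < H < G = N) is reporting-only and never enters
the binary call.

## The nucleation model

In the DAmFRET assay, expression rises monotonically over a ~16 h
induction, so a cell observed at final concentration $c$ has accumulated
nucleation risk while transiting all lower concentrations. For a linear
ramp and hazard rate $k\,c(t)^n$, the cumulative hazard is $K c^n$ with
$K = k\,t_f/(n+1)$ absorbed into the package's `kappa`. Self-poisoning —
the stalling of zipper growth when monomers arrive faster than they can
conformationally convert on the templating surface — is modelled as a
Hill-type suppression with a residual escape channel:

$$\Lambda(c) = K c^{n}\left[f_\mathrm{res} +
  \frac{1 - f_\mathrm{res}}{1 + (c/c_p)^{m}}\right],
\qquad P(c) = 1 - e^{-\Lambda(c)}.$$

The escape term reflects the observation that disordered, low-affinity
intermolecular contacts restore aggregation at high concentration; without
it ($f_\mathrm{res} = 0$) a pure Hill suppression either saturates (m ≤ n)
or decays to zero (m > n) and can never reproduce the observed
plateau-then-rise shape of fraction-positive curves. Defaults: `m_hill = 3`,
`f_resid = 0.15`, `c_poison = Inf` (poisoning off; the poisoned preset uses
30 µM).

Parameter defaults and their rationale:

| parameter | default | units | why |
|---|---|---|---|
| `c_range` | 1–200 | µM | the ~100-fold expression spread of the assay |
| `n_order` | 1 | — | the canonical reaction order of polyQ aggregation |
| `kappa` | 0.02 | µM⁻ⁿ | puts the half-nucleated point near 35 µM, mid-range |
| `template_factor` | 1 (preset `PINplus`: 100) | — | templated nucleation is frequent even at ~1 µM |
| `a_pos` | 0.35 (QU) / 0.60 (QB) | AmFRET | bilateral amyloid packs subunits more densely |
| `a_mid_frac` | 0.05 (QU) / 0.2 (QB) | — | growth-limited cells are commoner for slow-growing lamellar amyloid |
| `sigma_neg`, `sigma_pos` | 0.02, 0.06 | AmFRET | monomer scatter is narrow; assembled-state scatter broader |

## What the generator emulates, and what it does not

`generate_sample()` emits, per cell: a log-uniform final concentration, a
Bernoulli nucleation outcome from $P(c)$, an AmFRET value (monomeric ~
N(0, σ_neg); assembled ~ N(`a_pos`, σ_pos); a fraction `a_mid_frac` of
assembled cells at the intermediate level `a_pos`/2), and raw channels with
log-normal scatter distributions and linear gains chosen once so that the
standard printed gate coordinates pass essentially all events under the
default logicle transform (`acceptor = c·SSC·gain`, `fret = amfret ·
acceptor`, `donor ∝ c·SSC`). Derived concentration (acceptor/SSC) is
therefore exactly proportional to the true concentration.

Not emulated: spectral spillover and compensation (assumed applied
upstream; an instrument would require its own transform parameters),
instrument drift, doublets and debris (the cells/singlets gates pass nearly
everything by construction — their coordinates are honoured, not
stress-tested), cell-cycle or autofluorescence structure, and explicit
fibre growth/fragmentation dynamics (the intermediate population is an
emission-level approximation of growth limitation, and SDD-AGE size
distributions are not generated from kinetics). Passing tests therefore
demonstrate the correctness of the quantification machinery on data obeying
the stated model, not robustness to every artefact of real cytometry.

## DAmFRET quantification choices

* **Logicle**: own implementation of the biexponential scale; defaults
  T = 2²², M = 4.5, A = 0, W = 0.5, returned in decade units so the printed
  gate coordinates apply directly. Inversion is Newton iteration seeded by
  monotone interpolation; round trips are exact to well below 1e−6. Real
  instruments need their own (T, W, M, A).
* **Gate profile**: 64 log-spaced acceptor bins over 10⁵–10⁹ units (a
  deliberately wide fixed range), per-bin 99th percentile (linear
  interpolation between order statistics, the standard quantile default),
  invalid bins (centre below 2×10⁶ units, above the control's 99th acceptor
  percentile, or empty) filled from the nearest valid bin, 5-bin boxcar
  smoothing with symmetric window shrinkage at the edges, +0.028 shift,
  constant −0.2 lower gate. The invalid-bin acceptor percentile is taken
  from the control (the profile is control-derived); using each sample's
  own percentile is a noted alternative.
* **fgate**: events below the lower gate count in the denominator but never
  as positive. Events outside the binned acceptor range are clamped to the
  edge bins.
* **Intermediate fraction**: on above-gate events, a 1–2 component Gaussian
  fit (BIC-selected, `mclust`) estimates the upper mode; intermediate
  events lie between 3·σ_neg and (upper mean − 2·σ_upper). The boundary
  multipliers are configurable; the population-boundary definition in the
  underlying assay is not formalised, so this mixture rule is a stated
  substitute. The fit seeds its subsampled initialisation locally so the
  pipeline stays deterministic.
* **Reaction order**: weighted least squares of
  $\log(-\log(1-p))$ on $\log c$ over concentration bins with
  `min_n >= 25` events and $p \in [0.02, 0.95]$. The trimming matters: bins
  observed at exactly 0 or 1 drop off the scale, which selectively biases
  the surviving extreme bins; and binning on derived concentration rather
  than raw acceptor avoids attenuation from the cell-size spread.
* **Plateau detection**: a count-weighted smoothing spline (df ≈ 8) of the
  fraction-positive curve against log acceptor; a plateau is a run of ≥ 3
  bins whose slope falls below 0.2 of the running early-regime maximum and
  that is followed by a recovery above that threshold. A monotone
  saturating curve decays without recovering and is never flagged; an
  isotonic fit is returned alongside as the monotone baseline. Bins with
  fewer than 10 events are excluded — a one-event bin's fraction is noise —
  and the same ≥ 10 occupancy rule defines "occupied" wherever curves are
  compared across samples.

## Imaging and gel quantification

The puncta statistic is the printed definition sd/√mean with a strict
threshold of 30 — not the conventional coefficient of variation — so it
scales with the square root of detector gain; `cv_conventional` is reported
alongside, and the threshold is configurable because gain normalisation
upstream of the published threshold is not stated. Ellipse axes are used
verbatim as full lengths in the ellipsoid volume (4/3)·π·major·minor²,
exactly as printed. Rolling-ball background subtraction is grayscale
opening with a ball-height structuring element; runtime grows as the square
of the radius, so the synthetic gel fixtures use radii of tens of pixels
(the 200-pixel default matches full-size gel scans). Lane x-positions are
user-supplied; there is no automatic lane finding or molecular-weight
calibration.

## Problem sizes and determinism

The test suite exercises the stochastic stages at sizes chosen to make the
statistical assertions sharp while keeping a full run around a minute:
100,000-event negative controls (10 seeds) for the false-positive bound,
50,000 cells for reaction-order recovery, 20,000 cells per seed for
poisoning (10 + 10 seeds) and templating (5 seed pairs). All randomness
flows through explicit seeds (`withr::with_seed`); identical seeds give
byte-identical event tables and identical pipeline reports.

## Known limitations

The grammar is binary by design: it predicts competence, not nucleation
frequency, and ignores flanking-domain effects (e.g. huntingtin exon 1
context). The template-competence heuristic is compositional, not
structural. The poisoning functional form is phenomenological — it encodes
plateau location and steepness, not the underlying polymer-crystal
kinetics. The FCS writer/reader supports the float list-mode subset the
pipeline needs, not the full standard.
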