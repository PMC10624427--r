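# qzipper

Analytics for amyloid nucleation by polyglutamine (polyQ), the sequence whose
expansion beyond ~36 residues causes Huntington's and related
neurodegenerative diseases. The package is aimed at protein self-assembly
labs that (a) design polyQ sequence permutations and want the steric-zipper
grammar call for each, and (b) quantify nucleation frequencies from
single-cell DAmFRET flow cytometry, with supporting microscopy and SDD-AGE
densitometry.

## What it implements

**Q-zipper sequence grammar.** The polyQ amyloid core is a steric zipper:
two antiparallel β-sheets whose fully extended glutamine side chains
interdigitate and hydrogen-bond the opposing backbone. Because side chains
alternate 180° along a β-strand, zipper competence depends on glutamines at
every other position. The grammar computes, for a sequence s:

- *unilateral contiguity* U(s): the longest run of Qs at consecutive
  same-parity positions (one strand face; 5 Qs span 9 residues);
- *bilateral contiguity* B(s): the longest run of consecutive Qs (both
  faces, permitting lamellar growth);
- *intramolecular threading*: whether four strand windows of six residues
  fit into s with connecting loops of ≥ 4 residues (≥ 3 if all-glycine) —
  the monomeric nucleus geometry, giving the 4·6 + 3·4 = 36-residue polyQ
  threshold and a feasible 33-residue design with glycine loops;
- the binary *de novo competence* call: threading plus a propagating growth
  track (U ≥ 5 via single-face strands, or B ≥ 6 via fully-Q strands).

**Stochastic nucleation model and synthetic cytometry.** Nucleation is a
rare event while per-cell concentration c rises over induction. The
cumulative hazard is Λ(c) = K·cⁿ·[f_res + (1 − f_res)/(1 + (c/c_p)^m)], so
the fraction of nucleated cells at concentration c is P(c) = 1 − e^{−Λ(c)};
c_p is a self-poisoning midpoint (∞ disables it) and f_res the residual
growth channel that restores aggregation at high c. `generate_sample()`
emits full synthetic event tables (scatter, donor, FRET, acceptor,
autofluorescence channels) from this model, so every downstream stage is
testable without instrument data.

**DAmFRET quantification.** Logicle transform; the three sequential gates
(cells, singlets, expressing) with the standard printed coordinates; AmFRET
= FRET/acceptor and concentration = acceptor/SSC; a 64-bin negative-control
gate profile (per-bin 99th percentile, nearest-valid fill, 5-bin boxcar,
+0.028 shift, −0.2 lower gate); the `fgate` statistic; per-bin
fraction-positive curves with Wilson intervals; intermediate
(growth-limited) population fraction; top-decile median AmFRET; spline
curves; and self-poisoning plateau detection.

**Imaging and gels.** Sum projection, ROI statistics, the CV = sd/√mean > 30
puncta call, ellipsoid cell volume (4/3)·π·major·minor², per-cell
concentration; rolling-ball background subtraction, 10-pixel lane profiles,
integral normalization and lane summaries.

## Worked example

```r
library(qzipper)

seqs <- c(
  polyQ60 = strrep("Q", 60),
  Q4N     = make_repeat(4, "N", 60),   # (QQQQN) x 12
  Q5N     = make_repeat(5, "N", 60),
  nucleus = design_minimal_nucleus()   # Q6-GGG-Q6-GGG-Q6-GGG-Q6
)
classify_zipper(seqs, name = names(seqs))
#>     name length max_unilateral max_bilateral de_novo_competent architecture
#>  polyQ60     60             30            60              TRUE           QB
#>      Q4N     60              4             4             FALSE         NONE
#>      Q5N     60             30             5              TRUE           QU
#>  nucleus     33              3             6              TRUE           QB
```

Q4N interrupts every glutamine face (4 < 5 unilateral, 4 < 6 bilateral) and
cannot nucleate; Q5N keeps a complete alternating track (architecture QU);
the 33-mer design is competent only because its glycine loops sit exactly
between four fully-glutamine strands — mutating any single Q to N flips the
call to FALSE.

```r
control <- generate_negative_control(damfret_preset("negative_control", n_cells = 20000, seed = 1))
sample  <- generate_sample(damfret_preset("pinminus_QB", n_cells = 20000, seed = 2))
run_pipeline(control, list(Q60 = sample))$results
#>  sample n_expressing   fgate max_amfret intermediate_fraction plateau
#>     Q60        20000 0.36955  0.5823456             0.2199973   FALSE
```

`fgate = 0.370` is the fraction of expressing cells above the
concentration-binned negative-control gate; it recovers the generator's
true nucleated fraction (0.3695) to three digits. `max_amfret` is the
median AmFRET of the assembled population at top concentrations (≈ 0.6,
the bilateral preset's packing density), and 22% of positive cells sit at
intermediate AmFRET (the preset emits 20% growth-limited cells).

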