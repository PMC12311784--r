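---
title: "Annotating histone proteoforms from deconvolved mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating histone proteoforms from deconvolved mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoform)
```

## The problem

Histones of organisms without annotated genomes — reef-building corals are
the motivating case — cannot be annotated by ordinary database search:
there is no database. What a top-down experiment does provide is (i)
deconvolved intact-mass envelopes in which proteoforms appear as a ladder
of satellite peaks around a base mass, (ii) electron-capture dissociation
(ECD) fragment spectra that preserve labile modifications and read
sequence off c/z• ion ladders, and (iii) a derivatization-based bottom-up
workflow for orthogonal confirmation. `histoform` implements that whole
chain as composable, testable pieces.

The central object is the **proteoform**: one primary sequence plus one
exact set of localized modifications. Sites are 1-based on the processed
(initiator-Met-free) sequence, matching the conventional K5/K8/K12/K16/K20
numbering of the H4 tail; site 0 is the protein N-terminus, which may
carry at most one modification.

## Mass chemistry

All masses are monoisotopic and are computed from elemental composition
(C 12, H 1.0078250, N 14.0030740, O 15.9949146, S 31.9720710), so the
residue table is consistent with elemental arithmetic by construction.
Embedded constants (documented to six decimals): proton 1.007276,
water 18.010565, ammonia 17.026549, CO 27.994915.

Fragment ladders follow the standard series relations: `b` is the prefix
sum (plus modification deltas in span), `a = b − CO`, `c = b + NH3`; `y`
the suffix sum plus water, `z = y − NH3`, and `z• = z + H`. Both classic
`z` and radical `z•` are generated; ECD matching defaults to `z•`, which
electron capture predominantly produces. Fragment indices run 1..n−1:
full-length "fragments" are the precursor and are not emitted.
Complementarity (`b_i + y_{n−i} = M`, `c_i + z_{n−i} = M`) is asserted to
1e-4 Da in the test suite.

I and L are stored as distinct letters with equal mass; K and Q are
distinct residues 0.0364 Da apart. Equivalence handling (I≡L, K≡Q) lives
only in the de novo / homology layer, where it belongs.

## Explaining MS1 mass shifts

`build_delta_table()` enumerates every multiset of up to `max_ptms`
modifications (defaults: me1/me2/me3 = +14.0157/+28.0313/+42.0470, ac =
+42.0106, ox = +15.9949) together with all 380 ordered single-residue
substitutions. Numerically degenerate entries are kept on purpose — A→S
is elementally identical to oxidation, dimethylation is 0.025 Da from the
K→R substitution — because discriminating them is the job of either
sufficient MS1 accuracy or fragment evidence, not of the table.

`explain_mass_shift()` ranks entries by absolute error; ties (including
exact elemental ties such as me1 vs D→E, both +CH2) are broken
PTM-before-substitution, then lexicographically, so output order is
deterministic. Mass-silent substitutions (I↔L, delta 0) are excluded:
they can explain no shift. An empty result is a valid "unexplained"
return — deliberately so: one of the motivating datasets contains a
+26.27 Da envelope shift that matches no modification and no monoisotopic
residue exchange (the Ala−Pro difference is +26.016 Da), and the package
records such residuals rather than forcing a label.

Two defaults matter here: fragment-level matching is 10 ppm (the curation
tolerance of the source workflow) and envelope labeling is 0.02 Da,
matching the two-decimal reporting convention of deconvolved shifts.

Substitutions are modeled at MS1 stage as a replacement at *unknown*
position; position is assigned only by fragment evidence, which mirrors
how C- and N-terminal variants (A83S-style, R26K-style) are actually
localized.

## Candidate generation

`generate_candidates()` enumerates every localized placement of every
PTM multiset whose total delta matches the observed mass within 10 ppm,
under the site rules (ac: K or N-terminus; me1–3: K, R or N-terminus;
ox: M), one modification per site. The enumeration is exhaustive and
lexicographically ordered; a hard cap (default 10,000) guards against
combinatorial explosion and is always reported via a `truncated` flag,
never silently. Equivalence with naive exhaustive enumeration is asserted
in the tests for sequences up to 20 residues and 3 modifications.

Note that one observed delta can legitimately expand to distinct
chemistry: +70.042 Da is both ac+me2 and ac+me1+me1. Both are generated;
ranking against the spectrum decides.

## The four confirmation scores

Given matched fragments, the package computes

* **%SC** — sequence coverage: a residue is *confirmed* when both of its
  flanking backbone cleavage sites are evidenced by a matched fragment
  (termini count as evidenced). This flanking-cleavage reading is a
  design decision: the definition of "amino acid confirmed" is not
  otherwise pinned down, and a residue's mass is only determined between
  two observed cleavages.
* **%SVP** — sequence validation percentage: the confirmed residues in
  unbroken runs from the two terminals (disjoint prefix + suffix), over
  n. Always ≤ %SC.
* **%IC** — intensity coverage: the fraction of total peak intensity on
  peaks holding at least one match. Each observed peak is assigned to at
  most one theoretical fragment (smallest |ppm|; ties broken by lower
  charge, series order c, z•, z, b, y, a, then lower index), so intensity
  is never double-counted.
* **MS score** — %SC × %IC / 100, on a 0–100 scale.

The MS score is applied literally as the product formula. For one
published pair of inputs (92.74% SC, 65.77% IC) the formula gives 60.99
while the source prints 59.94; the vendor-side rounding or weighting
behind that difference is unknown, and this package does not try to
imitate it.

Candidate ranking is by MS score, then %SC, then fewer modifications —
the last tie-break encodes a mild parsimony preference among otherwise
indistinguishable isobaric explanations.

## Positional-isomer quantitation

Co-isolated positional isomers (K12ac vs K16ac is the canonical case)
share precursor mass and most fragments; only fragments between the two
modified sites differ. `find_reporter_ions()` computes, per group member,
the theoretical fragments farther than the ppm tolerance from *every*
fragment of *every* other member. `quantify_isomers()` then apportions
the group's MS1 envelope area by summed reporter intensity:

relative abundance(i) = (S_i / n_i) / Σ_j (S_j / n_j) × MS1 area,

where S_i is the member's summed matched reporter intensity and n_i its
theoretical reporter count. The count normalization is a deliberate
refinement of the plain intensity ratio: members of a 3+ group can have
very different numbers of distinguishing fragments, and the raw sum is
then biased toward reporter-rich members regardless of abundance (the
recovery simulations demonstrate mean errors near 0.18 without it). For
the two-member groups the source workflow actually quantified, reporter
counts are symmetric and the normalization changes nothing. No per-ion
pairing is attempted, and shared (non-reporter) intensity contributes no
correction — the source procedure states none.

One structural caveat: in a group of three or more isomers of a *single*
modification, the member whose site lies between its neighbours' sites
has provably no distinguishing fragment at all (each of its fragments
coincides with one neighbour's), so it is flagged unquantifiable rather
than estimated. Quantitation — and the recovery guarantee exercised in
the acceptance suite — applies to groups in which every member retains
reporters: all pairs, and staggered multi-modification layouts.
The MS1 area arrives as a scalar from envelope integration upstream;
integration bounds are out of scope. If no reporter of any member is
observed, the result is flagged unquantified rather than divided by zero.
Conservation (Σ relative abundance = MS1 area) is exact whenever
quantification happens, and is asserted over 10,000 random fixtures.

## De novo tags and homology identification

`extract_tags()` builds a spectrum graph on deconvolved fragment masses:
a directed edge joins two peaks whose gap matches a residue mass within
tolerance (default 0.01 Da), and every maximal path spells a tag. I/L is
emitted as "L"; K vs Q is decided by closest mass and flagged ambiguous
when the tolerance cannot separate the two (only possible when
tol > ~0.018 Da). PTM-tolerant edges (residue+modification gaps) exist
behind a flag but default off: modified gaps inflate the graph badly, and
tags from unmodified stretches suffice for identification.

`hsp_search()` performs the homology step as an ungapped local alignment
of every tag against every database protein under a fixed declared
scheme: match +2 (I≡L, K≡Q count as matches), mismatch −1, no gaps. HSPs
scoring ≥ 6 (three clean matches) are retained; a protein's total score
sums its best non-overlapping (subject-coordinate) HSPs across tags. The
published tool this emulates does not disclose its exact matrix, so these
scores are comparable *within* this artifact only — the tests therefore
assert rank recovery, not score values. Ambiguous tags contribute their
single best reading.

## Bottom-up confirmation

`propionylate()` implements the derivatization chemistry: round one labels
the protein N-terminus (unless already modified) and every K that is
unmodified or monomethylated — me1 retains a reactive proton, so me1-K
becomes the composite `me1prop` state, while ac/me2/me3 block the label.
This me1 behavior is standard derivatization chemistry adopted as a
documented decision. Round two labels only the peptide N-termini newly
exposed by digestion.

`digest()` applies trypsin on the derivatized protein, which behaves as
Arg-C: cleave after R, never before P, never at K. Both QC products of
the reference standard (GSTGGKAPR at 471.75²⁺ and GKAPATSGMVGPHR at
739.38²⁺ after full propionylation) fall out of exactly these rules, and
the acceptance suite checks them to the printed precision. Missed
cleavages default to 1 (the source leaves this unstated; 1 is the common
screening default) and are configurable.

`confirm_peptides()` filters spectra at ±0.01 Da on precursor m/z — the
monoisotopic stand-in for the precursor/isotope-profile check, envelope
fitting being out of scope — then scores b/y ladders with the same four
metrics.

## What the simulators emulate — and what they do not

The generators produce exactly the statistical structure the analysis
assumes: partial fragment ladders (Bernoulli sampling at a set
completeness), Gaussian ppm mass jitter, log-normal fragment intensities,
uniform-mass noise peaks whose intensity median is 10% of the signal
median, envelope peaks that collapse mass-degenerate isomers, and
chimeric isomer mixtures in which shared fragments add their
fraction-scaled contributions and each distinct mass is jittered once.
All randomness flows from the mandatory seed, and the generators
save/restore the global RNG state so callers are unaffected.

Defaults are fixed once: completeness 0.9 (the source's near-complete
ladders), jitter 2 ppm (well inside the 10 ppm curation tolerance), noise
fraction 0.1, intensity log-sd 0.5 (a realistic fragment-to-fragment
spread). Recovery tests use the harsher stated regimes (completeness
0.6–1, jitter up to 5 ppm, noise up to 0.3 for ranking; completeness 0.7
and noise 0.2 for isomer fractions).

They do **not** emulate: isotope envelopes or deconvolution artifacts,
ECD cleavage-propensity (completeness is position-independent, real ECD
is not), internal fragments, neutral losses, chimerism between
non-isomeric precursors, or mobility separation. A green recovery test
therefore establishes the *logic* of ranking and quantitation under the
assumed noise model, not instrument-grade performance.

## Numerical choices and degenerate inputs

* Tolerances: fragments 10 ppm, de novo gaps 0.01 Da (≈15 ppm at the
  relevant fragment masses), precursor 0.01 Da, envelope labels 0.02 Da,
  isomer grouping 0.01 Da.
* Peak lists must be strictly increasing; exact duplicate masses are
  merged by intensity summation at construction.
* Zero total intensity is an error for %IC; an empty spectrum yields
  all-zero scores instead of propagating 0/0.
* Empty explanation lists, empty reporter sets and unquantifiable groups
  are explicit flagged states, not errors.
* All enumeration orders (candidates, tags, HSP ties) are deterministic
  so identical inputs give byte-identical reports.

## Known limitations

Insertions/deletions are not modeled as mass-shift explanations (they are
not localizable from a shift alone). Average masses and isotope envelopes
are out of scope; inputs are assumed deconvolved and centroided. The CLI
reads JSON configuration only. Homology totals are scheme-internal
numbers. The candidate cap bounds worst-case enumeration; heavily
modified long proteins should be pre-constrained (by de novo evidence or
known PTM sets) before candidate generation, which is also how the
motivating workflow operated.
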