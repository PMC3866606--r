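---
title: "Methods: structure-based annotation of small proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based annotation of small proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sprotannot` reimplements, at desk scale, a structure-based annotation
pipeline for small proteins ("sproteins", 50–100 residues): model quality
assessment and confidence tiering, fold classification by structural nearest
neighbour, template-based protein–protein interaction (PPI) inference with a
statistically calibrated contact potential, and template-transfer prediction
of ligand and metal binding sites with fingerprint virtual screening. The
real inputs of such a study — a mammalian proteome, the PDB/CATH structure
libraries, compound collections — are replaced by seeded synthetic
generators, so every stage runs, and is testable, without downloads. The
generators are first-class, tested code: their planted ground truth is what
the acceptance checks recover.

# The structural data model and the backbone builder

Chains are ordered residues with backbone atoms N, CA, C, O (plus CB for
non-glycine) in Ångström coordinates; indexing is 1-based and sequential,
with author numbering discarded on read. All synthetic structures come from
one builder, `chain_from_torsions()`, which places atoms with a single table
of ideal covalent geometry (`ideal_geometry`: N–CA 1.458 Å, CA–C 1.525 Å,
C–N 1.329 Å; N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°; carbonyl O in the
carboxyl plane at 1.231 Å; CB at the L-configuration with the C–N–CA–CB
improper at +122.6°, verified against experimental structures). Torsion
convention: `phi[i]` = C(i−1)–N(i)–CA(i)–C(i), `psi[i]` =
N(i)–CA(i)–C(i)–N(i+1), and `omega[i]` is the peptide dihedral *preceding*
residue i, so phi/omega of the first and psi of the last residue are unused.
Re-measuring torsions on a built chain reproduces the inputs to well under
0.5°.

# Quality assessment

Three read-outs mirror the classic model-assessment trio:

* **Secondary structure** is assigned from backbone hydrogen bonds with
  DSSP-style pattern rules (two consecutive n-turns give G/H/I; bridge
  patterns give E, isolated bridges B; turn neighbourhoods T; priority
  H > E > G > I > B > T > C). Backbone H-bonds use the DSSP electrostatic
  energy, E = 0.084·(1/rON + 1/rCH − 1/rOH − 1/rCN)·332 < −0.5 kcal/mol,
  with amide hydrogens constructed geometrically (1 Å from N on the
  C(i−1)/CA bisector). We require sequence separation ≥ 3 for
  backbone–backbone bonds: the assignment rules never consult closer pairs,
  and at separation 2 an ideal extended strand produces spurious
  sub-threshold contacts. Side-chain bonds (when side-chain atoms are
  present) use a geometric criterion: donor–acceptor ≤ 3.5 Å and a
  donor-antecedent angle ≥ 90°.
* **Hydrogen-bond pattern** is reported as per-residue counts in three
  categories (main–main, main–side, side–side).
* **Stereochemistry** is a Ramachandran-region lookup in a 10°×10° grid
  generated in code from explicit rectangles: core α, core β, core
  left-handed α, each surrounded by 20° ("additional allowed") and 40°
  ("generously allowed") bands; everything else is disallowed, with glycine
  capped at "generously allowed". Shipping the grid as a versioned code
  fixture keeps the classification reproducible without external data.
  Region fractions are reported over classifiable non-glycine, non-terminal
  residues (the denominator is a documented package choice).

Model confidence is an *input* to the pipeline (the upstream threading
stage that estimates it is out of scope): `confidence_tier()` maps an
estimated TM-score to high (≥ 0.7), moderate (≥ 0.4), low, or none (no
estimate). In the synthetic benchmark the estimate is the measured TM-score
of the model against its true source fold.

# Structural classification

`tm_score_fixed()` computes the length-normalized TM-score,
d0 = max(0.5, 1.24·(L−15)^⅓ − 1.8), maximized over rigid transforms by
iterative Kabsch fitting on shrinking inlier subsets (full pair set plus
sliding windows; inliers re-selected inside a distance cutoff each round).
`align_structures()` is a deterministic TM-align-family heuristic: seeds
from gapless threading offsets, secondary-structure string alignment, and
the best 15-residue fragment pair, each refined by alternating the
TM-optimal superposition with dynamic-programming re-pairing on the score
1/(1+(d/d0)²) (gap open 0.6, no extension penalty; compiled in C++). The
reported TM-score is normalized by query length — the pipeline asks
"how much of the small protein is explained" — and the refinement never
returns less than the best seed (a tested greedy-improvement property).
`classify_by_nearest()` transfers the Class.Architecture.Topology label of
the best library hit when its TM-score is ≥ 0.4, the conventional
significance threshold; ties break by aligned sequence identity, then entry
id, so searches are reproducible.

# Interaction inference

The PPI stage composes five ingredients:

1. **Binding-residue prediction** — an empirical surface-patch score,
   u = 0.5·propensity(aa) + 0.3·exposure + 0.2·(neighbourhood mean of u),
   with a shipped 20-entry interface-propensity table (aromatics and large
   hydrophobics high, small polars low). Exposure is linear in the CB
   neighbour count within 10 Å, anchored so the least-buried residue scores
   1 with a fixed slope (24 excess neighbours = fully buried) — a fixed
   scale keeps patches comparable across chains. The prediction is the top
   25% of surface residues (exposure > 0.3).
2. **Template usability** — a dimer template is used only when its ligand
   chain aligns to the model at TM ≥ 0.4 *and* the template interface,
   mapped through the alignment, overlaps the predicted binding patch at
   MCC ≥ 0.5 (universe: all model residues).
3. **Receptor mapping** — each template receptor's position profile is
   aligned (affine gaps, free ends) against every proteome sequence; the
   score is standardized against ≥ 100 seeded shuffles of the same sequence
   and mapped through a fixed logistic, plogis(z − 3); candidates above 0.5
   are kept with their threading alignment.
4. **Contact potential** — a quasi-chemical log-odds table over
   cross-interface CB contacts (≤ 8 Å, CA for glycine),
   e(a,b) = −ln[(n(a,b)+1)/(N·f(a)·f(b)·g)], symmetric by construction.
5. **Energy and probability** — the modeled complex is evaluated in the
   template's geometry: the template's own contact map is scored with amino
   acids read through the two alignments, divided by the number of distinct
   interface residues. (Re-measuring contacts after rigidly re-placing the
   model was rejected: backbone noise of moderate-quality models then
   dominates the sequence signal.) Energies of the template library's own
   complexes are fitted with a Gaussian; the interaction probability is the
   upper-tail fraction p = 1 − Φ((E−μ)/σ), and pairs at p ≥ 0.5 are called,
   taking the best probability over usable template × receptor-candidate
   combinations.

# Binding-site annotation

Holo templates passing the TM ≥ 0.4 gate donate their ligand centroid or
metal position through the alignment's rigid transform; transferred centers
are clustered (average linkage, 8 Å cut), pockets are ranked by summed
member TM-score, and site confidence is a fixed logistic,
plogis(3·support_fraction + 4·mean_TM − 3.5) — constants are configuration,
not fitted, since only the ≥ 50% gate is consumed downstream. Screening
builds the pocket's consensus fingerprint (per-bit mean) and ranks
compounds by the generalized Tanimoto Σmin/Σmax; the screen is confident
when the top compound's Z-score against the library score distribution is
≥ 2. Libraries can be deduplicated greedily at Tanimoto 0.8. Metal sites
add a TM-weighted majority vote over member metal types (conf_type = the
winner's vote share), a chemistry filter for coordinating residues (e.g.
Zn: C/H/D/E; Ca/Mg: D/E/N/Q/S/T plus backbone O), and a residue-agreement
confidence (the mean fraction of each member's transferred coordination
shell that lands on the reported binding residues). The three confidences
are independent channels.

# The synthetic benchmark

Noise is applied in torsion space, never Cartesian: Gaussian perturbation of
phi/psi followed by an ideal-geometry rebuild keeps bond lengths and angles
realistic, so QA stages see plausible backbones at every quality level.
Model-quality tiers use noise levels of 2° (high), 8° (moderate) and 25°
(low), drawn at the cohort fractions observed in the motivating study
(10/39/42/9% high/moderate/low/no-model); 2° was calibrated once so that
≥ 90% of 60-residue models stay above TM 0.7.

Dimer templates are built by folding two chains and rigidly docking the
smaller against the larger along a random approach axis, backing off until
no inter-chain CA pair is closer than 3.8 Å, and requiring at least 13
(strong parents) or 8 (background) interface residues per side. Three
design choices make the planted interaction signal detectable *by
construction*, which is the point of a planted-truth benchmark:

* docking presents a protruding ligand face to the receptor (interfaces
  form on exposed patches);
* interface residues are rewritten with complementary "sticky" pairs
  (hydrophobic–hydrophobic and salt-bridge pairs) at rate 0.9 in strong
  parents, 0.15 in background dimers, while non-interface positions are
  depleted of the six strongest interface-prone residue types;
* a strong parent is accepted only if the binding-residue score recovers
  its interface on the clean ligand chain at MCC ≥ 0.6 — model noise is
  then the only degradation the pipeline faces.

Strong parents use six distinct fold variants (two mainly-α, one mainly-β,
three α/β) whose pairwise TM-scores sit below or near the 0.4 gate, so
cross-template confusions are rare and must additionally pass the MCC and
probability gates. The proteome plants one homolog per strong receptor by
point mutation (rate 0.2) among random background sequences of 50–600
residues. The fold library for classification is built around the *actual*
source folds (loop torsions are random per realization, so two independent
builds of one spec are different folds). Holo templates are mildly
perturbed copies of the query fold carrying a site on a protruding surface
anchor; for metals, both the templates and the query fold receive a
chemically apt coordination shell (within 6 Å CA, at least the four nearest
residues) — the modeling target is itself a binder.

What the generators do **not** emulate: real side-chain packing and rotamers
(chains carry only CB), evolutionary sequence covariation (point mutations
only), real compound chemistry (fingerprints are abstract bit vectors), and
crystallographic artifacts. Passing tests therefore demonstrate that the
pipeline's logic recovers planted signal through the stated gates, not that
it reaches any particular accuracy on real proteomes.

# Numerical choices and degenerate inputs

* Multi-strand sheets: hairpins are closed with a two-residue turn,
  (30°, −150°) / (−50°, 0°), found by a one-off grid search to maximize
  cross-strand H-bonding of the ideal-geometry backbone; meanders beyond
  four strands accumulate twist and are avoided in the shipped fold specs.
* d0 is clamped at 0.5 Å (the formula turns negative below 22 residues);
  alignments with fewer than 5 matched pairs report TM 0.
* MCC is defined as 0 whenever a marginal factor vanishes; the universe is
  all model residues.
* Gaussian calibration refuses fewer than 30 finite energies or σ < 1e−6;
  a screening library with zero score variance raises an error rather than
  returning an unusable Z-score.
* All generators are pure functions of (parameters, seed) via an internal
  RNG-state guard; identical calls are bit-identical, and the pipeline's
  stage seeds are derived from the run seed.

# Problem sizes

The default benchmark runs 18 modeled small proteins against a 36-dimer
template library (6 strong parents + 30 background), a 30-sequence proteome
(24 background + 6 planted homologs), a 6-topology × 3-member fold library,
5 holo templates per binding target and compound libraries of a few hundred
to ~1,000 fingerprints. These sizes give stable recovery statistics while a
full run completes in a few minutes on one CPU; all of them scale up through
`make_benchmark()` arguments.

# Known limitations

* The alignment heuristic is not a full fragment-assembly TM-align; on hard
  topology pairs it can undershoot the optimum (it is tested to stay within
  the greedy-improvement and truth-pairing bounds).
* Binding-site localization on moderate-quality models occasionally
  misregisters by a helix turn or strand shift; the pipeline reports these
  honestly rather than filtering them.
* The profile mapper is a profile-to-sequence aligner with a shuffle null —
  a stand-in for HMM–HMM comparison that preserves the stage contract
  (probability gate + threading), not its sensitivity.
* Estimated model confidence is taken from the benchmark manifest; ranking
  models without a reference structure is out of scope.
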