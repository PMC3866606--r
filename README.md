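# sprotannot

Structure-based functional annotation of small proteins ("sproteins",
50–100 residues) in R. Short open reading frames encode thousands of small
proteins whose functions are mostly unannotated; because many of them have
no detectable sequence homologs, annotation has to go through structure:
model the protein, place it in fold space, and transfer function — binding
partners, ligands, metals — from structural templates.

`sprotannot` implements that pipeline at desk scale, for method developers
and for teaching:

* **Model QA** — DSSP-style secondary structure from backbone H-bonds
  (electrostatic criterion E = 0.084·(1/r<sub>ON</sub> + 1/r<sub>CH</sub> −
  1/r<sub>OH</sub> − 1/r<sub>CN</sub>)·332 < −0.5 kcal/mol), H-bond category
  counts, Ramachandran region fractions, and confidence tiers from an
  estimated TM-score (high ≥ 0.7, moderate ≥ 0.4).
* **Fold classification** — TM-score structure alignment
  (d0 = max(0.5, 1.24·(L−15)<sup>1/3</sup> − 1.8), query-length
  normalization) against a labeled library; the best hit's
  Class.Architecture.Topology label transfers when TM ≥ 0.4.
* **Interaction inference** — an empirical binding-residue score, a
  template-usability gate (TM ≥ 0.4 and interface-overlap MCC ≥ 0.5),
  profile-based receptor mapping with a shuffle-null z-score, a
  quasi-chemical contact potential e(a,b) = −ln[n(a,b)/N·f(a)·f(b)·g], and
  Gaussian-calibrated interaction probabilities
  p = 1 − Φ((E−μ)/σ), called at p ≥ 0.5.
* **Binding annotation** — template-transferred ligand/metal site centers,
  average-linkage clustering at 8 Å, pocket confidence, Tanimoto
  virtual screening with a Z ≥ 2 confidence rule, library deduplication at
  Tanimoto 0.8, and metal-type voting with three independent confidence
  channels.
* **Synthetic benchmark** — seeded generators that emulate every external
  dataset (quality-tiered models, dimer templates with labeled interfaces,
  proteomes with planted receptor homologs, labeled fold libraries, holo
  templates, fingerprint libraries), with planted ground truth as a
  first-class output.

The methods vignette (`vignettes/methods.Rmd`) documents every model,
threshold and design choice.

## Worked example

Generate a benchmark and run every stage:

```r
library(sprotannot)
bm  <- make_benchmark(seed = 42, n_sproteins = 8, n_strong = 4,
                      n_weak = 26, n_background = 12)
rep <- run_pipeline(benchmark = bm, seed = 42, n_binding_targets = 2)
rep
#> <run_report>
#>   tiers: high=1 moderate=5 low=1 none=1
#>   classification: 6/6 correct
#>   interactions: 4 called, precision 1.00, recall 0.67, bg rate 0.000
#>   binding targets: 2
```

Eight sequences were modeled; one model is high-confidence (estimated
TM ≥ 0.7), five moderate, one low, one had no model. All six confident
models received the correct fold label. The interaction stage called four
(sprotein, receptor) pairs at probability ≥ 0.5:

```r
subset(rep$interactions$map$calls, called)
#>   sprotein     receptor template     energy probability called
#> 1 sprot001 hom_strong01 strong01 -0.4442530   0.8432366   TRUE
#> 2 sprot003 hom_strong03 strong03 -0.2420379   0.5156457   TRUE
#> 5 sprot005 hom_strong01 strong01 -0.4442530   0.8432366   TRUE
#> 7 sprot008 hom_strong04 strong04 -0.3806389   0.7590140   TRUE
```

`energy` is the per-residue contact-potential score of the modeled complex
(lower = more favorable); `probability` is its upper-tail position in the
Gaussian fit to the template library's own complexes. All four calls are
planted homolog pairs (precision 1.0); two planted pairs were missed
(recall 0.67), one at the TM gate and one at the probability threshold.

Binding annotation on the two most confident models:

```r
b <- rep$binding$sprot005
round(b$pockets[[1]]$site_confidence, 2)  # 0.92  (>= 0.5: high confidence)
round(b$pocket_error, 2)                  # 0.46  A from the planted site
round(b$screening$z_top, 2)               # 7.69  (>= 2: confident screen)
b$metal$metal_type                        # "MG", matching the planted metal
round(c(b$metal$conf_site, b$metal$conf_residues, b$metal$conf_type), 2)
#> 0.93 0.90 1.00   # three independent confidence channels
```

The top-ranked pocket sits 0.46 Å from the planted site with 92% site
confidence; screening ranks the planted actives first with Z-score 7.7; the
metal channel recovers the planted magnesium site to 0.8 Å with the correct
type.

A command-line wrapper with the same behaviour lives at
`inst/scripts/run_pipeline.R`.

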