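---
title: "Deciding genuine ACS activity from motif architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding genuine ACS activity from motif architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsarch)
```

## The scientific question

1-aminocyclopropane-1-carboxylate synthase (ACS) catalyses the
rate-limiting step of ethylene biosynthesis, converting
*S*-adenosyl-methionine (SAM) to ACC. Plant genomes are full of
ACS-*like* genes — PLP-dependent enzymes of the aspartate
aminotransferase (AAT) fold superfamily that include aminotransferases
and C–S lyases — and sequence similarity alone does not predict which of
them are *genuine* ACSs, i.e. actually make ACC. A sequence-level
decision rule separates them:

> a protein is predicted to be a genuine ACS **iff** it carries all
> nine conserved ACS motifs, in their canonical N-to-C order and
> without overlap, **and** the glutamine equivalent to AtACS7 Q98
> (inside motif 2, reaching into the partner subunit's active site),
> **and** the asparagine equivalent to AtACS7 N217 (a PLP-contacting
> residue whose absence explains the one known motif-complete inactive
> protein).

`acsarch` implements that rule end to end — motif discovery and
scanning with exact p-values, ordered-architecture assessment,
key-residue mapping by global alignment, the conjunctive classifier —
together with the supporting analyses used to establish and validate
such a model: neighbor-joining phylogenies with bootstrap support and a
monophyly test, and crystal-structure superposition with active-site
extraction. Everything is exercised on a synthetic protein-family
generator with complete ground truth.

## Motif models and exact p-values

A motif is an ungapped position probability matrix over the 20 standard
amino acids. From aligned instances, probabilities are
`(counts + pc*bg) / (nsites + pc)` with a background-proportional
pseudocount (total `pc = 0.375` by default, a standard choice for
protein motifs), and scores are log-odds in bits against a background
model (`estimate_background()` uses maximum likelihood with +1
pseudocounts per letter, so no letter has probability zero).

Scanning uses **exact** position p-values: the log-odds matrix is
quantised to an integer grid (1000 bins per bit), and the null
distribution of the window score is computed by column-wise convolution
over the background. Quantisation always rounds scores *down*, so tail
p-values are conservative. A window is a hit when its p-value is at or
below the position threshold (default `1e-4`, the conventional
motif-search cutoff; no principled value is fixed by the biology, so it
is exposed in `acs_config()`). Ambiguous letters (X, B, Z, J, U, O)
contribute zero bits, and windows more than half ambiguous are skipped.
The per-sequence best hit additionally carries a Sidak-corrected
sequence-level p-value `1 - (1 - p)^m` over the `m` scanned windows;
on background-only sequences these are super-uniform (the test suite
checks this at n = 2000 with a one-sided Kolmogorov–Smirnov test).

```{r pmf-demo}
bg <- uniform_background()
m <- build_motif_model(c("WWCHYKQW", "WWCHYKQW", "WWCHYAQW"), bg,
                       motif_id = "demo")
d <- score_distribution(m, bg)
sum(d$pmf)          # exact distribution: total mass 1
```

## Discovery: ZOOPS expectation-maximisation

`discover_motifs()` re-implements greedy sequential discovery in the
style of MEME: for each candidate width, ZOOPS (zero-or-one occurrence
per sequence) EM runs from seeded starts; the best motif is kept,
its occurrences probabilistically erased, and the search repeats.
Several design choices matter and are worth stating plainly:

* **Candidate widths.** Trying every width from 6 to 50 buys little; the
  default grid is `{6, 8, 11, 15, 21, 29, 38, 50}`, and exact widths can
  be passed when known.
* **Seeding.** Starting points are actual subsequence windows. A pool of
  candidates (weighted by erasure retention) is scored by the likelihood
  after one EM step, and full EM runs only from the best few — this is
  what prevents convergence to shifted local optima.
* **Polish and shift refinement.** After EM, the hard site set is slid
  as a block to the offset maximising its log-likelihood ratio
  (penalised by erasure retention, so erased occurrences stay
  unattractive), and one EM refit from the realigned model recovers
  members a shifted optimum left below the posterior cutoff.
* **Pruning and trimming.** Each site must beat the background against a
  leave-one-out model with the same pseudocount smoothing the model
  itself uses — this removes the classic ZOOPS artefact where a junk
  site sustains itself with weight `1/nsites` per column. Edge columns
  with less than ~1.5 nats of evidence per site are trimmed, so a wide
  candidate cannot keep absorbed flanks (and its erasure cannot damage a
  neighbouring motif).
* **Significance.** A motif is kept while its site log-likelihood ratio,
  charged `log(windows + 1)` per occupied sequence for the occurrence
  configuration and `(K-1)/2` nats per column for the expected
  maximum-likelihood overfit of one column on background, stays
  positive. On a degenerate input (all one letter) nothing clears the
  floor and discovery returns no motifs.
* **Numerics.** Per-position erasure weights enter the likelihood
  through cumulative sums of logs; the `log(0)` sentinel is kept at a
  moderate magnitude (−10⁴ per position) because a ±10³⁰⁰-scale
  cumulative sum destroys the precision of differences between nearby
  entries — i.e. of every window weight downstream of an erased region.

## Architecture and the decision rule

`assess_architecture()` keeps, per required motif, the lowest-p-value
hit (ties to the smaller start) and declares the architecture complete
when all nine are present, their starts strictly increase in motif
order, and no two kept hits overlap. The AAT motif — characteristic of
the aminotransferases — is reported independently and never vetoes
(there is no evidence it should). `check_key_residues()` maps the
reference positions (98 and 217 in AtACS7 numbering, initiator Met = 1)
through a global affine-gap alignment (BLOSUM62, gap open 11, extend 1,
end gaps penalised; deterministic traceback diagonal > up > left) and
reports match / mismatch(letter) / deleted.

The classifier conjoins completeness, order, Q98 and N217. The
asparagine is a hard conjunct by default because the single known
motif-complete inactive protein is explained precisely by its absence;
`strict_n217 = FALSE` restores the two-level presentation in which that
case is annotated rather than rejected, and every motif-complete,
glutamine-positive, asparagine-negative sequence carries an exception
note either way. Cβ–S lyase activity is reported as "not determined by
this model": the nine motifs are not all necessary for it, and no
positive lyase rule is defined. Every output row carries a stable hash
of the full configuration.

Interfaces follow the field's conventions: FASTA in/out via Biostrings,
motifs in MEME minimal text format (`read_meme()` / `write_meme()`), a
TSV evidence table with `+`/`−` glyphs and a JSON hit report, Newick
trees, and PDB structures via bio3d. All user-facing coordinates are
1-based inclusive.

## The synthetic family generator

`family_spec()` / `sample_family()` generate protein families of
420–480 residues that emulate the validation design: positives carry
the nine ACS motifs in order; negatives deviate by exactly one missing
motif, a scrambled order (motif 9 traded with motif 1), a Q→A or N→A
point mutation, a lyase-like member with only the seven C-terminal
motifs, or an aminotransferase-like control carrying the AAT motif.
Ground truth (labels, planted positions, key-residue status) is exact.

Choices a user should know, with the reasoning:

* **Consensus strings are random per seed** (widths 12–24 summing to
  ~150 residues for the nine motifs, AAT 14), so no test depends on any
  published motif table. An independent family of the *same* protein
  family (same consensus, fresh instances) can be drawn for training via
  the `consensus` argument — `run_benchmark()` does exactly that.
* **Motif columns**: the consensus letter appears with probability `c`
  exactly (off-consensus letters are drawn from the background
  *excluding* the consensus letter), and the two key-residue columns are
  always planted, so labels remain derivable from the rule at any `c`.
* **Whole-chain homology.** ACS-like proteins are homologous over the
  entire AAT fold, not just at motifs, and the published tree separates
  subfamilies. Inter-motif regions therefore descend from a family
  scaffold with their own conservation (default 0.5 — enough linker
  homology to carry the family's shared ancestry into distances, still
  well below motif-column conservation) plus light per-sequence indels
  (10% deletion, 10% insertion) so linkers are homologous but not
  frame-locked — without the indels, frame-locked linkers let EM merge
  adjacent conserved blocks into one motif. Junction lengths are 5 +
  geometric (mean 25): a zero-length junction would collapse two motifs
  into one block, contradicting the architecture being planted. The structural control
  classes (`seven_only`, `aat_control`) carry additionally diverged
  scaffolds (50% retention) and their own N-terminal regions, emulating
  the lyase-like and aminotransferase-like subfamilies; the point-mutant
  classes keep the family scaffold, so they are true point mutants.
  An early version drew linkers i.i.d. per sequence; that makes the
  positives' tree signal (the ~39-residue motif-1/2 region) undetectable
  against ~280 random columns and misrepresents the biology, so it was
  replaced by the scaffold model.
* **Calibration.** `empirical_composition_check()` chi-squares the
  letters the generator actually drew i.i.d. from the background
  (scaffold, substitutions, padding — tallied during generation; pooled
  spacer letters are scaffold-correlated across sequences and would
  invalidate the test) and estimates realised motif conservation with
  its binomial error.

What passing on this generator does **not** show about real data: real
families have site-rate heterogeneity, realistic amino-acid
composition, longer-range indel structure and correlated substitution
processes; motif instances in real proteins are not column-independent.
The generator is a control experiment for the *pipeline*, not a model
of molecular evolution.

## Phylogeny

`progressive_msa()` is a deliberately simple, deterministic progressive
aligner (pairwise-identity guide tree by UPGMA, affine-gap
profile–profile merges with sum-of-pairs BLOSUM62 scores) standing in
for production aligners; tree claims are therefore validated as
topological properties, never as branch-length matches.
`distance_matrix()` offers p-distance and its Poisson correction
`-ln(1 - p)` with pairwise deletion (saturated pairs are an error, not
a silent NaN). `neighbor_joining()` wraps the standard Saitou–Nei
algorithm (via ape), clamping negative branch-length estimates to zero
and recording the originals. `bootstrap_support()` resamples columns
with replacement with a counter-based seed (`seed + replicate`), so any
replicate is reproducible in isolation; supports are percentages of
replicates containing each internal bipartition of the full-data tree.
`is_monophyletic()` asks whether one edge separates the label set from
its complement (singletons and complements of singletons are trivially
monophyletic); it is cross-checked against an independent
implementation in the tests.

On two-subfamily benchmarks at conservation 0.9 the classifier-positive
set is monophyletic in ≥ 95% of seeded runs, and at 200 bootstrap
replicates the genuine-ACS bipartition attains high support — the
tree-level echo of the observation that only functional ACSs carry the
key glutamine.

## Structures

`read_structure()` parses PDB text (bio3d underneath; mmCIF is
rejected with a clear error since no R reader is available), resolving
alternate locations to the highest-occupancy conformer (ties to the
alphabetically first). `kabsch_superpose()` is a single-pass
least-squares rigid fit by SVD with reflections excluded — no iterative
outlier rejection, which would change printed comparisons
unpredictably. Pairing is by residue number within an entry and by
global sequence alignment across different proteins; CA atoms by
default. `active_site()` lists residues with any non-hydrogen atom
within a radius (default 4.0 Å; no radius is fixed by the source data)
of a named het group, flagging residues from the partner subunit — the
cross-subunit glutamine's situation. `compare_regions()` restricts the
fit to a residue list, optionally in a frozen global frame.

`reproduce_printed_rmsds()` encodes the six published comparisons for
the AtACS7/MdACS1 structures (0.76, 0.44, 0.83, 0.176, 0.59, 0.12 Å)
and recomputes them from the deposited files when present; a ±0.1 Å
agreement band reflects the unstated superposition conventions of the
original comparisons. The deposited coordinates cannot be bundled with
the package, so the shipped validation rests on
`perturb_coordinates()`: a random displacement field orthogonalised
against the six rigid-body modes and rescaled (by root finding on the
measured value) until the post-superposition RMSD equals a target
within 1e-9 — fixtures at exactly the published magnitudes. The Kabsch
result is also checked against a quaternion-search oracle to 1e-4 Å.

The reference sequence shipped in `inst/extdata` is a **synthetic**
AtACS7-like stand-in (generator-built, Q at 98 and N at 217 by
construction), not the real AtACS7; `check_key_residues()` accepts any
reference, so the real sequence can be dropped in where real data are
analysed.

## Problem sizes and reproducibility

The shipped analyses use a 100-sequence benchmark family (50 positives,
50 negatives across six classes) for classification, 12-sequence
two-subfamily benchmarks for trees (20 seeded runs; 200 bootstrap
replicates), 100 random additive matrices of up to 6 taxa for NJ
consistency, n = 2000 null sequences for p-value calibration, and
50 random point sets for the superposition oracle — sizes chosen so the
full validation reruns comfortably on a laptop. Every stochastic stage
requires an explicit seed (absence is an error, not a silent default),
and `scripts/acceptance.R --seed <int> --out <path>` reruns the whole
validation and writes the quantities as JSON.

## Known limitations

* Motif thresholds for "presence" are conventions, not fitted values;
  real-sequence reproductions should report threshold sensitivity
  (classification at `1e-3`–`1e-5` is one line of config away).
* The progressive aligner is adequate for benchmark families, not a
  substitute for a production MSA tool on deeply diverged real data.
* Discovery's width grid and significance charges are heuristics tuned
  for block-like protein motifs; motifs much weaker than ~1.5 nats per
  site per column will be trimmed away by design.
* No gapped or profile-HMM motifs; homolog search is out of scope — the
  pipeline accepts candidate FASTA directly.
* Quantitative activity levels are outside the model: the rule predicts
  a binary genuine-ACS call, nothing about rates.
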