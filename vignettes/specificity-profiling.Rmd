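---
title: "Profiling protease specificity from phage substrate display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protease specificity from phage substrate display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageprof)
```

## The experiment this package models

A phage substrate display campaign asks a protease which residues it
prefers around the bond it cleaves. Nonamer peptides spanning subsites
P5…P4′ are displayed between a His-tag (used to immobilize the phage)
and the pIII coat protein; protease treatment releases exactly those
phages whose displayed peptide it can cleave. Iterating
immobilize–cleave–amplify over a few rounds enriches the best
substrates, and sequencing a sample of clones from the last round gives
an aligned pool of selected 9-mers. Everything downstream of the
sequencer is what `phageprof` implements.

## The enrichment model

### Library null

The randomized cassette uses NNK degenerate codons: position-wise
alphabets {A,C,G,T} × {A,C,G,T} × {G,T}, 32 equiprobable codons, all 20
amino acids represented, one stop (amber, TAG). `amino_acid_background()`
derives P(x) by enumerating and translating the codon set. Two stop
policies exist because display libraries are usually propagated in
amber-suppressor hosts:

* `exclude_renormalize` (default): a stop codon yields no displayed
  peptide, so the 31 coding codons are renormalized — P(Trp) = 1/31,
  P(Leu) = P(Ser) = P(Arg) = 3/31. This is the conservative model for
  *functional* (displayed) clones and the default throughout.
* `amber_as_gln`: in supE hosts TAG is read as Gln, giving
  P(Gln) = 2/32. Offered because suppression efficiency in practice is
  partial and unknown; the choice shifts every P(x) by at most 1/31 −
  1/32 ≈ 0.001 and barely moves the z-scores.

Constrained designs fix P1: `X4-R/K-X4` uses an ARG codon
(Arg/Lys, 0.5/0.5) and `X4-Y/F-X4` a TWT codon (Tyr/Phe). A `W/F`
alias for the latter is accepted, since cassette naming in construction
records sometimes uses it; the TWT codon itself encodes Tyr/Phe either
way.

### Scores

For residue x at position i, `delta_sigma()` computes

$$\Delta\sigma_{i,x} = \frac{Obs_i(x) - n P_i(x)}{\sqrt{n P_i(x) (1 - P_i(x))}}$$

the z-score of the observed count under the binomial null
Binomial(n, P_i(x)). Under no selection it has mean 0 and SD 1 at every
cell, which makes cells comparable across positions and libraries and
gives "number of standard deviations of enrichment" its literal
meaning; the test suite checks this calibration against Monte-Carlo
binomial draws (10⁵ draws; mean and SD within 0.05).

Cells the library cannot produce — the 18 non-Arg/Lys residues at a
fixed P1, say — have P(x) = 0 and no null distribution. They are
*masked*, never scored, and `delta_sigma()` refuses p ∈ {0, 1} rather
than returning an infinity.

### Normalization

PSSM-style scanning wants scores on a bounded scale; we use −5…+5. The
default is one **global** linear factor, 5/max|Δσ| over all unmasked
cells: zero maps to zero, sign and within- and across-position ranking
are preserved, and the additive window score keeps a meaningful unit.
A per-position variant (`scope = "per_position"`) is available for
matrices whose positions differ wildly in depth, at the cost of
cross-position comparability — with additive scoring we consider the
global map the defensible default.

Masked cells need a sentinel for the scanner. The default
(`mask_policy = "neutral_zero"`) writes 0: a residue the library never
offered the protease carries *no evidence*, and penalizing it would
forbid predictions that fixed-P1 campaigns demonstrably make (a
chymotrypsin-like profile built on a Y/F library still predicts, and
experiment confirms, cleavages with other P1 residues). The
`hard_exclude` policy (−5) is provided for users who want predictions
confined to the library's P1 chemistry.

An all-zero matrix (no selection signal at all) is returned unchanged
with a warning rather than dividing by zero.

## Scanning and the topology filter

`scan_protein()` scores every bond with a complete 9-residue window —
P1 from residue 5 to L−4, i.e. L−8 windows; terminal bonds are not
padded, because the model is only defined on full windows. The window
score is the additive sum of per-position normalized scores; additivity
is also what makes the default threshold of 10 interpretable (two
strongly preferred residues, or several moderate ones). Non-standard
residues (X, B, Z, U) void only the windows containing them. Output
order is deterministic: descending score, then protein id, then P1
index; `scan_proteome()` pools per-protein hits, ranks globally and
truncates to the best 500 by default.

Exogenous proteases only reach the extracellular face of membrane
proteins, so predictions are filtered by topology. The containment rule
is deliberately minimal: **both P1 and P1′ must lie inside a single
annotated extracellular interval**. The recognition window may straddle
the ectodomain boundary — it is the scissile bond that must be solvent
exposed, and a whole-window rule would wrongly reject sites sitting a
few residues from the membrane (the curated reference table bundled
with the package contains exactly such a site, four residues from the
end of its ectodomain). Curation steps that need human judgement —
dropping hypothetical proteins, privileging immune-related targets —
are *not* automated; `shortlist()` takes an explicit exclusion list and
carries a free-text curation column.

One site in the bundled reference table is published with a cleavage
*position range* rather than a single bond; it is transcribed with P1
at the nonamer's P1 position inside that range, which leaves every
accounting number unchanged (any position in the range is deep inside
the ectodomain).

## ELISA validation statistics

Cleavage efficiency is the fractional loss of immobilizable phage
signal, ΔA/A = 100·(A_u − A_t)/A_u; it is invariant to the absorbance
scale. Two calls are computed separately, because they answer different
questions and conflating them is a known source of confusion in
screening reports:

* **efficiently cleaved**: mean ΔA/A strictly greater than 10%
  (strict, so a mean of exactly 10 is not called);
* **significantly cleaved**: exact two-sided Mann–Whitney test of the
  replicate efficiencies against the negative control at α = 0.05. With
  the typical two-experiments-in-duplicate layout (4 vs 4 replicates)
  the smallest attainable p is 2/70 ≈ 0.029, so significance is
  meaningful but coarse.

SEM is sd/√r over the declared replicate structure; the package does
not guess how wells nest into experiments.

## The simulator: what it emulates, and what it does not

`simulate_library()` draws i.i.d. peptides from the design background —
the composition of a freshly synthesized cassette. `simulate_selection()`
models one round as independent Bernoulli elution per phage with
probability logistic(β₀ + β₁·s), s the peptide's score under a planted
ground-truth matrix; the no-protease control arm uses s = 0, giving the
round's enrichment rate; the eluate is re-amplified to constant pool
size by resampling with replacement; rising stringency can decrement β₀
per round. Defaults β₀ = −4 (a score-0 phage elutes with p ≈ 1.8% per
round, the background-release regime), β₁ = 0.5, 3 rounds, 75 clones
sequenced.

The logistic link is the simplest monotone map from additive PSSM score
to per-round cleavage probability — chosen for transparency, not
mechanism. The simulator ignores display valency, infection kinetics,
amplification bias, sequencing error and codon-level mutation; inter-
peptide competition enters only through resampling. Consequently,
passing the recovery tests shows the *statistical pipeline* inverts the
*assumed* selection model at realistic sizes — it does not certify
performance on real campaigns, where the null P(x) itself may deviate
from NNK theory (empirical library sequencing can replace it: profile
the naive pool and feed measured frequencies into a custom design).

`simulate_proteome()` plants the truth matrix's consensus window at
known P1 coordinates inside (or deliberately outside) generated
ectodomains, so scan and filter have exact expected answers.
`simulate_elisa()` adds Gaussian well noise (SD in percent of the ~1.0
untreated signal, default 2%) to both arms.

### Parameter recovery, and why shallow sequencing gives coarse profiles

The headline property test simulates a 10⁴-phage fully randomized
library, 3 rounds, sequences 2000 survivors, rebuilds the matrix and
compares with truth: Spearman ρ ≥ 0.7 over unmasked cells and ≥ 80%
top-residue agreement at strongly selected positions (truth score ≥ 3).
At the realistic sequencing depth of 75 clones the same campaign must
still reach ρ ≥ 0.4: with n = 75 a residue at the NNK null is expected
only ~2.4 times, so single-clone fluctuations move Δσ by ~0.65 SD units
— profiles at this depth rank preferences usefully but argmax residues
are unstable, which is exactly how published phage-profiling matrices
should be read.

These problem sizes (10⁴ phages, 2000/75 sequenced, 10⁵ Monte-Carlo
draws, proteins ≤ 50 residues for the exhaustive scan oracle) were
chosen to make every property measurable in seconds while keeping the
estimates' own noise well below the acceptance bands.

## Numerical and format choices

* Matrix TSV: 9 labelled rows (P5…P4p), 20 alphabetical residue
  columns, masked cells as `NA`, values printed with `%.10g` — 10
  significant digits parse back to a double that reprints identically,
  so write→read→write is byte-identical.
* Background probabilities must sum to 1 within 1e−9 per position
  (checked at design construction).
* Ties: scan output ordered by (−score, protein id, P1 index);
  `set.seed()` before every stochastic stage; `run_pipeline()` derives
  per-stage seeds from one master seed and records them with input
  checksums in a JSON manifest, so identical configs give byte-identical
  artifact bundles.
* Degenerate inputs fail loudly: empty pools, wrong-length peptides
  (with index), non-standard residues, inverted topology intervals
  (with row), zero control counts, selection extinction.

## Known limitations

* The additive PSSM score is the minimal model consistent with
  threshold-based scanning of a −5…+5 matrix; subsite cooperativity
  (non-additive pairs such as P2–P1′) is not modelled, and the scoring
  strategy is isolated in `score_window()` precisely so it can be
  swapped.
* Whether published campaign matrices used theoretical NNK backgrounds
  or empirically measured library frequencies is generally not
  recoverable from the matrices themselves; both paths are supported
  and neither is assumed.
* The topology filter is only as good as its interval annotations; no
  transmembrane prediction from sequence is attempted.
* Reported per-protease "confirmation" fractions depend on which call
  (efficiency vs significance) a report used; `confirmation_summary()`
  therefore exposes the >10% operationalization explicitly and keeps
  the significance flag separate.
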