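---
title: "Methods: branch point utilization analysis of 3' splice site minigene libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch point utilization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpmpra)
```

## The assay and its in-silico counterpart

The package analyses a two-acceptor splicing reporter: a single intron
whose weak 3′ splice site (SA1) is flanked by two fully degenerate 25-nt
regions (N25A intronic, immediately upstream; N25B exonic, just
downstream), with a dominant acceptor SA2 exactly 156 bp downstream of
SA1 and a unique 20-bp barcode read out in R2 of a paired-end run. Which
degenerate sequences rescue SA1 — and how that differs between a
wild-type and a K700E-mutant SF3B1 background — identifies the branch
point (BP) preferences of each spliceosome.

Because no external dataset ships with the package, a generative
simulator is a first-class component: it encodes the hypothesized mutant
mechanism (tolerance of non-canonical bases at the −1 position of the
U2–BP duplex) as a single parameter, and every downstream statistic is
validated by recovering that mechanism from simulated data.

## Scaffold geometry

`scaffold_config()` fixes the invariant backbone. Published reporter
descriptions pin the SA1–SA2 spacing (156 bp), the insert lengths (25
nt), the barcode length (20 bp), and the base construct's canonical
CTAAC branch point with its adenosine 29 bp upstream of the acceptor
(`base_minigene()` reproduces this). The remaining distances are package
choices:

* N25A ends 7 nt upstream of SA1, separated by an invariant
  pyrimidine-rich heptamer `TTTCCAG` ending in the acceptor AG. Keeping
  SA1's immediate acceptor context invariant means 6-mer statistics see
  only degenerate sequence.
* N25B begins 10 nt downstream of SA1.
* Invariant intronic filler is built from adenosine-free `CTTCG` repeats
  so that the only BP candidates upstream of SA1 lie inside N25A, and
  SA2's BP search window contains exactly one invariant canonical branch
  point (`ACTAACTTC`, adenosine 29 bp upstream of SA2, mirroring the base
  construct's geometry at SA1).

Coordinates are 0-based and half-open throughout; an acceptor position is
its first exonic base; the reporter is plus-strand only.

## The U2–branch point duplex model

A BP candidate is a 9-mer with the nucleophilic adenosine at the fifth
base, treated as bulged out of an antiparallel duplex with the U2 snRNA
recognition hexamer 5′-GUAGUA-3′. Window positions −4, −3, −2, −1 and +1
pair with U2 bases U, G, A, U, G. The free energy is

ΔG = Σ nearest-neighbor stacks over consecutive paired positions
   + Σ per-position mismatch penalties + bulge term,

clamped at 0 for non-binding windows (the clamp can be disabled via
`duplex_energy(clamp = FALSE)`; strict ordering properties are stated on
unclamped values, since two windows clamped to zero tie by construction).

Numerical choices, all in `duplex_params()`:

* **Stacks** are Turner 2004 nearest-neighbor values (kcal/mol, 37 °C)
  for the steps reachable against the fixed U2 strand, kept in a single
  table so the model is swappable. The tandem-wobble GU/UG step is
  destabilizing (+1.3) in that parameter set and is floored at 0: in this
  model stacking may only stabilize, which the mismatch-monotonicity
  property (degrading a position never lowers ΔG) requires.
* **Wobbles**: G·U pairs are accepted at −4 and at the two pyrimidine
  consensus positions (−3, +1), matching the YTAAY consensus in which
  either pyrimidine pairs canonically or as a wobble.
* **The −1 position** is where the biology lives. A non-adenosine at −1
  is modeled as a *modified* pair: the helix and its stacking are
  maintained (stacks are scored as if the canonical A were present) and
  the entire destabilization is a lumped penalty (default 6 kcal/mol,
  covering both lost stacking and the mismatch cost). The mutant
  condition scales exactly this penalty by λ ∈ [0, 1]. Treating the −1
  mismatch as helix-breaking instead would remove ~3.5 kcal/mol of
  stacking that no tolerance mechanism could restore, making −1-variant
  BPs inert in *both* conditions; the modified-pair treatment reflects
  the mechanistic picture in which the mutant spliceosome accommodates
  altered −1 pairing within an intact duplex.
* **Bulge term** 0.5 kcal/mol: the branch adenosine's extrusion is
  largely paid for by the protein clamp around the duplex, so only a
  small residual cost is charged; a full single-bulge penalty (~3.8)
  would push even decent windows above the clamp.
* **Penalties** elsewhere: 2 kcal/mol (−3, −2, +1) and 1 kcal/mol at the
  peripheral −4.
* `predict_bp()` scans adenosine-centred windows with BP offsets in
  [−50, −10] of the acceptor and returns the minimum-ΔG candidate; exact
  ties break toward the acceptor-proximal position.

With these values the best canonical window (`GCTAAC` core context)
scores −7.6 kcal/mol, a perfect-context −1 variant −1.3 (wild type) or
−4.9 (K700E at λ = 0.4). Three properties are enforced exhaustively over
all 4^8 A-centred windows in the test suite: mismatch monotonicity; mode
ordering ΔG(K700E) ≤ ΔG(WT) with equality exactly for canonical −1; and
YTAAY-core optimality (the global minimum is attained by, and only by,
YTAAY-core windows). Energies here are model scores for ranking and
comparison; they are not calibrated to absolute duplex energies from a
full secondary-structure tool.

Descriptive analyses (e.g. `sa1_energy_comparison()`) use a single
energy model with λ = 1 for both genotype groups, so reported energy
differences reflect sequence content, not the scoring mode.

## The acceptor-competition model

For each minigene, candidate acceptors are SA1, SA2 and every AG
dinucleotide inside a degenerate region with ≥ 6 nt of downstream room
(novel acceptors). Each candidate receives a log-weight

w = β_bp · (−ΔG_best) + β_ppt · f_py + baseline,

where ΔG_best is its best BP candidate in the search window (with λ
applied in the K700E condition), f_py the pyrimidine fraction of the 20
nt immediately upstream, and the baseline is `sa2_bonus` for SA2, 0 for
SA1, `novel_penalty` for novels. Probabilities are the softmax of the
log-weights; transcript counts are multinomial draws at a per-minigene
Poisson depth (mean 50 by default).

Defaults (β_bp = 1 per kcal/mol, β_ppt = 2, sa2_bonus = −0.5,
novel_penalty = −2, λ_K700E = 0.4) were calibrated once so that random
libraries reproduce the marginal behaviour reported for this reporter
class — SA2 predominant, SA1 near 2% of wild-type transcripts, novel
acceptors a minor fraction, and mutant SA1 usage clearly elevated — and
then frozen. At the packaged demonstration scale (20,000 minigenes,
depth 50) a run yields WT SA1 ≈ 1.5%, K700E ≈ 2.1% (1.4-fold), twice as
many K700E-only as WT-only SA1 minigenes, and a −1-variant share among
differential enhancers ~3.5× its census background. With λ = 1 the two
conditions are identical by construction, which the null-calibration
tests exploit.

## What the simulator does and does not emulate

Emulated: barcoded library structure with i.i.d. uniform inserts;
condition-dependent acceptor competition through BP energetics and
polypyrimidine content; junction-spanning R1 / barcode-bearing R2 read
pairs with i.i.d. substitution errors and Phred+33 dummy qualities; full
seeded determinism (identical configuration and seed give byte-identical
FASTQ).

Not emulated: PCR duplicates and amplification bias; indels; position- or
quality-dependent error profiles; nonsense-mediated decay (single-intron
reporter); cellular variation in SF3B1 dosage. The generative model also
gives N25B no causal role in acceptor choice (it contributes novel
acceptor candidates only), so 25B 6-mer statistics act as a built-in
negative control rather than a model of downstream enhancers. Passing
recovery tests therefore demonstrates that the statistics detect the
encoded mechanism at realistic depth and noise — not that real libraries
are free of the unmodeled effects.

## Demultiplexing and filtering rules

* Barcode assignment: exact match wins; otherwise the unique barcode
  within Hamming distance ≤ 1 (configurable); ties and misses are
  unassigned. Duplicate barcodes abort index construction.
* Junction calls: a read must match one isoform reference (exon 1 joined
  to the acceptor's downstream sequence) with ≤ 1 substitution at an
  offset covering the junction by ≥ 15 nt on each side, and that best
  isoform must be unique; everything else is uncalled. A transcript is a
  read pair — no UMI collapsing.
* Representation filter: a minigene is kept only if it reaches 5 summed
  reads in *every* condition; the filter is idempotent and monotone in
  the threshold.
* Odds ratios use a Haldane–Anscombe pseudocount of 0.5, keeping log2 OR
  finite for 6-mers that are rare at desk scale.

Under the hierarchical motif census (TAA, then T[CGT]A, then [ACG]AA,
then both-variant, then none), 705/4096 = 17.2% of all 6-mers are
−1 variants — the roughly one-in-six background against which enhancer
enrichment is judged.

The pipeline can run its two simulated conditions either through full
FASTQ emission and demultiplexing (`sequencing = TRUE`) or directly on
the simulated transcript tables; with error-free sequencing the two
routes agree exactly (tested), so large-scale runs default to the direct
route and the round-trip equivalence is demonstrated at the
thousand-minigene scale.

## Validation problem sizes

The shipped test suite validates at sizes chosen to keep the full run in
the minutes range on one CPU: exact brute-force odds-ratio recounts on
twenty fixtures of 80–500 minigenes; a 1,000-minigene zero-noise FASTQ
round trip with 100% truth agreement; ten 1,500-minigene sequence-blind
(β = 0) simulations showing no motif-class enrichment at α = 0.01; one
20,000-minigene recovery run for the directional mutant signatures; and
the exhaustive 4^8 energetics sweep. The pipeline's summary report flags
"no condition effect" when the SA1 fold change is within ±0.25 log2
units of 1, about 3.5 standard errors at the demonstration depth.

## Known limitations

The BP predictor is a declared energetic heuristic, not a trained model;
its energies rank windows but are not physical duplex energies. The
−1 penalty and bulge term are lumped effective parameters. Results are
specific to this two-acceptor geometry (acceptors 156 bp apart) and do
not extrapolate to much closer or more distant acceptor pairs. All
statistics treat minigenes as exchangeable: there is no modeling of
plasmid copy number, transfection efficiency, or expression covariates.
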