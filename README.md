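# bpmpra

Branch point utilization analysis for barcoded 3′ splice site minigene
libraries.

## The problem

Cancer-associated mutations in the splicing factor SF3B1 (canonically
K700E) cause spliceosomes to select novel ("cryptic") 3′ splice sites,
typically 15–30 bp upstream of the canonical acceptor. SF3B1 stabilizes
the duplex between U2 snRNA and the intronic branch point (BP), so the
leading mechanistic hypothesis is a change in BP selectivity — but BPs are
degenerate and hard to observe directly. A massively parallel reporter
assay (MPRA) sidesteps this: a library of minigenes, each with two
competing splice acceptors (a weak SA1 flanked by two 25-nt degenerate
regions, and a dominant SA2 exactly 156 bp downstream) and a unique 20-bp
barcode, is expressed in wild-type and mutant cells and read out by
paired-end sequencing. Which degenerate sequences rescue SA1, and how
that differs between genotypes, reveals the BP preferences of each
spliceosome.

`bpmpra` implements the full analysis stack for this assay type, plus a
generative simulator encoding the mutant mechanism, so every statistic
can be exercised and validated end-to-end without external data:

* **Simulation** — seeded minigene library generation
  (`generate_library()`), an acceptor-competition model
  (`acceptor_weights()`, `simulate_transcripts()`), and paired-end FASTQ
  emission with a truth sidecar (`emit_reads()`).
* **Demultiplexing** — barcode assignment with Hamming-distance rescue
  (`match_barcode()`), junction-spanning acceptor calls
  (`call_junction()`, `build_transcript_table()`), and the
  minimum-representation filter (`apply_filters()`).
* **Usage statistics** — transcript- and minigene-level acceptor
  fractions (`usage_fractions()`), the shared / mutant-only / wild-type-only
  partition of SA1-utilizing minigenes (`partition_sa1()`), and upstream
  context matrices for novel acceptors (`novel_ss_context()`).
* **6-mer odds ratios** — for each of the 4096 6-mers, the odds ratio of
  its presence in SA1-utilizing vs non-utilizing minigenes
  (`kmer_or_stats()`), the between-condition contrast
  Δlog2OR = log2OR(K700E) − log2OR(WT) (`delta_log2()`), enhancer ranking
  (`top_enhancers()`), and a hierarchical BP motif classifier
  (`classify_kmer()`, `classification_census()`).
* **Energetics** — a nearest-neighbor model of the U2 snRNA–BP duplex
  (`duplex_energy()`), heuristic BP prediction over 9-mer windows with the
  branch adenosine at the fifth base (`predict_bp()`), and Wilcoxon
  comparison of energy distributions (`compare_energies()`,
  `sa1_energy_comparison()`).
* **Orchestration** — a configured, seeded, manifest-logged pipeline
  (`run_config()`, `run_pipeline()`) with a rendered markdown report
  (`render_report()`).

## The core statistic

For a 6-mer *m* and a degenerate region (25A upstream or 25B downstream
of SA1), count minigenes in the filtered universe:

|              | contains *m* | lacks *m* |
|--------------|--------------|-----------|
| uses SA1     | a            | b         |
| does not     | c            | d         |

OR(*m*) = ((a + p)(d + p)) / ((b + p)(c + p)) with Haldane–Anscombe
pseudocount p = 0.5. 6-mers with OR > 1.5 are splicing enhancers; ranking
them by Δlog2OR(K700E − WT) and classifying each by the BP trinucleotide
it contains (TAA canonical; T[CGT]A = −1 variants; [ACG]AA = −2 variants;
both; none — first match wins) asks *which kind of branch point the
mutant spliceosome gains*. The mutant mechanism enters the simulator
through a single parameter λ ∈ [0,1] that scales the −1-position penalty
of the U2–BP duplex, encoding tolerance of modified −1 base pairing.

## Worked example

```r
library(bpmpra)
lib <- generate_library(2000, scaffold_config(), seed = 42)
wt  <- simulate_transcripts(lib, "WT",    splice_model_params(lambda_minus1 = 1),   depth = 50, seed = 1)
mut <- simulate_transcripts(lib, "K700E", splice_model_params(lambda_minus1 = 0.4), depth = 50, seed = 2)
tabs <- apply_filters(list(WT = wt, K700E = mut), min_reads = 5)

us <- usage_summary(tabs$WT, tabs$K700E)
round(us$K700E$transcript_fractions, 4)
#>    SA1    SA2  NOVEL
#> 0.0206 0.9741 0.0053
us$sa1_fold_change
#> [1] 1.400086

partition_sa1(tabs$WT, tabs$K700E)
#> 514 SA1-utilizing minigenes: 28.6% shared, 48.1% K700E-only, 23.3% WT-only
```

SA2 dominates, SA1 captures ~2% of transcripts, and the mutant condition
both uses SA1 more (1.4-fold here) and owns twice as many exclusive SA1
minigenes as wild type. Which sequences drive the difference:

```r
d <- delta_log2(kmer_or_stats(lib, tabs$WT,    region = "25A", condition = "WT"),
                kmer_or_stats(lib, tabs$K700E, region = "25A", condition = "K700E"))
enh <- top_enhancers(d, or_threshold = 1.5, by = "delta")
head(enh$table[, c("kmer", "log2_or_wt", "log2_or_k700e", "delta_log2", "motif_class")], 5)
#>     kmer log2_or_wt log2_or_k700e delta_log2    motif_class
#> 1 GCTGAT -0.3674349      6.829054   7.196488 MINUS1_VARIANT
#> 2 ACTTAC -1.2166511      5.958543   7.175194 MINUS1_VARIANT
#> 3 GGGCTG -1.0093648      5.748374   6.757739           NONE
#> 4 GCTTAC  0.3749543      6.935934   6.560979 MINUS1_VARIANT
#> 5 ACTGAC -0.4771808      5.210452   5.687632 MINUS1_VARIANT
```

The top mutant-differential enhancers are −1 variants of the canonical
YTAAY branch point (CTGAC, CTTAC, …): sequences that barely help SA1 in
wild type but strongly enhance it under K700E. Their predicted U2–BP
duplexes are correspondingly weaker:

```r
sa1_energy_comparison(lib, tabs$WT, tabs$K700E)
#> U2-BP duplex energies: shared mean -4.447 (n=147) vs k700e_only mean -0.964 (n=247)
#> Wilcoxon rank-sum p = 9.98e-48; less stable set: k700e_only
```

The whole analysis is also available as one call:
`run_pipeline(demo_config(seed = 1))` (20,000 minigenes; writes every
artifact, a manifest and `report.md` to the configured output directory).

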