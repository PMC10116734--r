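# mavecall

Simulation and low-frequency SNP/MNP calling for saturation-mutagenesis
(MAVE) targeted sequencing, in R.

## The problem

Multiplexed assays of variant effect (MAVEs) quantify thousands of engineered
variants in one transcript by deep sequencing of pooled libraries. Each
variant is present at an ultra-low frequency (often 10⁻⁴–10⁻³), far below the
raw error rate of short-read sequencing, so an ordinary variant caller
drowns in false positives. `mavecall` is for analysts of such experiments —
typically NNK codon-mutagenesis libraries sequenced with tiled amplicons or
RACE-like (anchored multiplex PCR) preparations — and provides both halves of
the methodology:

* **sim** — a deterministic spike-in simulator that edits requested SNPs and
  MNPs (1–3 nt substitutions) into pre-existing paired-end reads at exact
  target frequencies. For a variant *v* with target frequency *f* and
  fragment coverage *C* at its position, `round(f·C)` fragments (minimum 1)
  are sampled uniformly among fragments that cover the full allele, carry no
  pre-existing mismatch within a buffer *b* (default 3 nt) of the edit, and
  are not already edited — so a spiked variant can never merge with a
  neighbouring error into a higher-order allele ("variant conversion"), and
  no fragment is edited twice. A truth VCF records realized counts and
  frequencies.

* **call** — an end-to-end caller: (optional) UMI extraction → alignment →
  (optional) UMI directional-adjacency consensus deduplication → (optional)
  primer base-quality masking → mismatch enumeration requiring **mate
  concordance** (both reads of the pair must report the same non-reference
  base with quality ≥ *q*) → greedy merging of phased mismatches into MNPs
  while the merged reference span is ≤ 3 nt → aggregation into per-variant
  counts and frequencies (supporting fragments / fragment coverage at the
  variant position) with codon and protein annotation, the NNK-signature
  flag, and per-mismatch quality features (median base qualities, read
  positions, edit distances per mate, strand counts).

Around the callers sit a machine-learning error-correction layer (balanced
truth sets simulated into a negative-control library; random forest, GBM,
elastic-net GLM, kNN and SVC classifiers under nested 10-fold
cross-validation; per-call error probabilities used as a filter) and a
post-calling filter chain (target region → NNK signature → single-codon →
type-specific counts → strand bias → classifier → replicate agreement) with
negative-control log₁₀-frequency subtraction.

A synthetic-data module (`make_reference()`, `simulate_library()`,
`build_validation_dataset()`) generates amplicon and RACE-like libraries with
UMIs, PCR duplicates, substitution-biased error profiles and a full
provenance ledger, so every claim the package makes is testable without any
external data.

## Worked example

Simulate an error-free 2,000-pair library over a random 50-codon transcript,
spike in one SNP at 0.5% and one di-nt MNP at 1%, and call them back:

```r
library(mavecall)
library(tibble)

ref <- make_reference(50, seed = 7)
design <- library_design("amplicon", read_len = nchar(ref$sequence))
lib <- simulate_library(ref, design, 2000, error_profile(), seed = 1)
aln <- ledger_alignments(lib)

specs <- tibble(
  pos = c(30L, 61L), ref = c("A", "CT"), alt = c("G", "GA"),
  target_frequency = c(0.005, 0.01)
)
plan <- plan_edits(specs, aln, ref, seed = 1)
edited <- apply_edits(plan, aln)
edited$truth[, c("pos", "ref", "alt", "coverage", "realized_count",
                 "realized_frequency")]
#> # A tibble: 2 × 6
#>     pos ref   alt   coverage realized_count realized_frequency
#>   <int> <chr> <chr>    <int>          <int>              <dbl>
#> 1    30 A     G         2000             10              0.005
#> 2    61 CT    GA        2000             20              0.01

res <- run_call(edited$reads, ref,
                call_filters(min_count = 2, min_bq = 30, max_nm = 10))
tidy(res)[, c("pos", "ref", "alt", "variant_type", "count", "coverage",
              "frequency", "aa_change")]
#> # A tibble: 2 × 8
#>     pos ref   alt   variant_type count coverage frequency aa_change
#>   <int> <chr> <chr> <chr>        <int>    <int>     <dbl> <chr>
#> 1    30 A     G     SNP             10     2000     0.005 Val10Val
#> 2    61 CT    GA    di_nt_MNP       20     2000     0.01  Leu21Glu
```

The simulator placed exactly `round(f·C)` fragments per variant (10 and 20),
and the caller recovered both variants with those exact supporting counts
and frequencies: the SNP is a silent Val10Val change, the MNP a Leu21Glu
missense change. `glance(res)` summarises the run (2 calls from 2,000 pairs,
50 concordant mismatches); `run_call(..., outdir = )` additionally writes a
VCF, a per-mismatch summary table (one row per mismatch participating in a
primary call — do not double-count), and a fragment-coverage bedgraph.

A thin command-line wrapper with `synth`, `sim` and `call` subcommands is in
`inst/cli/mavecall.R`; the `call` flags mirror the package filters
(`-m/--min-count`, `-q/--min-bq`, `-e/--max-nm`, `-s/--signature`,
`-p/--primers`, `-d/--dedup`, `-u/--umi-pattern`).

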