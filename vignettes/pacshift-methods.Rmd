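---
title: "pacshift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pacshift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pacshift` analyses 3'-end sequencing (PAS-seq) data for alternative
polyadenylation (APA): reads carrying polyA tails mark cleavage sites; sites
are quantified and clustered into polyA-site clusters (PACs); per-gene PAC
usage is compared between a treatment and a control to call 3'UTR shortening
or lengthening; sequence context around cleavage sites is profiled for
polyadenylation signals; antisense PAC production and functional enrichment
of shifted genes are tested. Every stage is exercised against a synthetic
generator that knows the ground truth it planted.

Alignment of real reads to a real genome is out of scope: the package
consumes alignments (GRanges / BED / BAM) and ships only a deliberately small
exact-match mapper (`map_reads()`) so the synthetic benchmark runs without an
external aligner.

# The read-trimming model

A PAS read is `body + polyA tail (+ sequencing errors)`. `trim_polya()`
anchors the 3'-most run of at least `anchor_len = 8` consecutive A, removes
everything from the anchor to the read end, and then keeps clipping 5'-ward
across A-rich sequence until it meets at least `stop_non_a = 2` *consecutive*
non-A bases, which remain in the body. Bodies longer than
`min_body_len = 11` nt (strictly) are kept.

Two readings of the "two non-A bases" stop rule are possible: consecutive, or
cumulative within a window. The consecutive reading is implemented because it
matches the rule's evident purpose — an isolated sequencing error inside the
tail (an `A -> C` substitution, say) must not stop the clip, while genuine
genomic sequence, which rarely pauses for only one non-A base, should. The
3'-most qualifying A-run is chosen as anchor because the tail is by
construction terminal; genomic A-runs further 5' must not trigger clipping.
Reads with no 3' anchor can optionally be retried in reverse-complement
orientation (`scan_5prime`), which handles mate-orientation reads whose tail
appears as a 5' T-run; the forward orientation wins ties.

A kept body never ends in an anchor run (the clip stops only at >= 2 non-A
bases), which is the idempotence property the trimmer guarantees. A body may
still *contain* an A-run of anchor length further 5' of the removed anchor;
re-trimming such a body is not meaningful and the pipeline never does it.

# Quantification

* site TPM (tags per million): `count * 1e6 / total reads in the sample`, so
  a complete site table sums to 1e6;
* gene RPKM: `count * 1e9 / (gene length * total reads)`;
* categories: a site is assigned by same-strand feature overlap with priority
  `3'UTR > CDS > 5'UTR > intron`; a site overlapping a gene only on the
  opposite strand is `antisense`; anything else `intergenic`. The priority is
  a design choice (the protocol targets 3' ends, so 3'UTR dominance is the
  correct tie-break); no downstream 3'UTR extension is applied by default
  (`utr3_extend = 0`), keeping just-past-TTS sites intergenic unless the user
  opts in.

Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) and
BED (0-based half-open) are converted at the boundary by `read_annotation()`
and `extract_sites()`. Multi-isoform gene models are unioned per gene.

# PAC clustering

Within one sample, sites with TPM strictly above 0.5 are chained by single
linkage with an inter-site gap of at most 20 nt (distance clustering in the
CAGE tradition). Across samples, clusters whose spans are within 100 nt
edge-to-edge are merged; the consensus span is the union and the
representative position (`rep_pos`) is recomputed from pooled member-site
counts, ties broken to the most 3' position on the cluster's strand (the
distal cleavage base — a deterministic, biologically sensible tie-break).

Two filters reflect the two analysis modes: `apa` drops clusters with a
single member site, plus clusters below 3 TPM in *every* compared sample
(keeping a cluster supported in at least one condition preserves
condition-specific PACs, which are exactly the APA signal — the stricter
"below 3 in any sample" reading would delete them); `combined` keeps
clusters with pooled TPM of at least 5. Threshold boundaries are literal:
`> 0.5`, `>= 3`, `>= 5`; all are configurable in `cluster_params()`.

Whether the 20-nt rule bounds gaps or total cluster width, and whether the
100-nt rule measures edge gap or representative distance, are genuinely open;
gap-based single linkage was chosen for both because it is order-invariant,
has a clean transitive-closure definition that a brute-force oracle can
verify, and reduces to the alternative for the narrow clusters that dominate
real data.

# Shift detection

For each gene with at least two APA-filtered sense PACs expressed in both
conditions, member-site TPM weights are laid on the transcript's 3'-oriented
axis and normalized (`gene_site_distribution()`). The shift score is the
Kolmogorov–Smirnov D statistic between the two usage cumulatives — 0 for
identical usage, 1 for disjoint point masses. The same statistic feeds the
significance test, which makes score and test self-consistent; the exact
weighting used by upstream tag-cluster tools is not published, so defining
the score as the KS sup-distance is this package's design decision.

Effective KS sample sizes are the per-gene supporting *read counts* per
condition (TPM values are normalized, not counts), capped at
`cap_n = 1000` so sheer depth cannot manufacture significance. P-values use
the asymptotic Kolmogorov distribution with the Stephens small-sample
correction; when the pooled support is at most `exact_max = 20` reads the
exact permutation distribution is enumerated instead. The truncated
asymptotic series is clamped to 1 below lambda = 0.2, where the survival
probability is 1 to machine precision. Because the data are discrete
(ties abound), the asymptotic test is conservative — its observed null
false-positive rate is well under the nominal 1%.

Per gene the caller reports: direction (movement of the usage-weighted mean
cleavage position along the 3' axis — downstream is `lengthening`), distance
(between the dominant, highest-TPM PAC representative positions of the two
conditions), ORF impact (a dominant PAC in CDS, or dominance moving between
CDS and 3'UTR), and significance at raw `p < 0.01` — the method's stated
convention; BH adjustment is available (`shift_params(fdr = TRUE)`) but off
by default. Genes whose significant shift distance exceeds 50 nt are flagged
`motif_eligible` for the signal analysis below.

# Sequence signals

`extract_windows()` returns the 100-nt transcript-oriented window
`[-50, +50)` with offset 0 at the cleavage base (minus-strand sites are
reverse-complemented; chromosome edges are N-padded and flagged).
`base_composition()` gives per-offset A/C/G/T frequencies with N excluded
from denominators. `hexamer_scan()` counts *overlapping* k-mer occurrences at
every start offset (k = 6, top 30 by default) — overlap counting is
deliberate: homopolymer signals such as the downstream `AAAAAA` element and
the all-T background then rank first, matching how such scans are usually
read. `call_peak()` declares a k-mer present in a region when its maximum
in-region count reaches `fold_threshold = 2` times its median count outside
(the median is floored at 0.5 so empty profiles cannot divide by zero and
flat profiles are never "present").

For shifted genes, each gene beyond the 50-nt distance filter contributes its
control-dominant PAC window to one group and its treatment-dominant window to
the other (`shifted_pac_windows()`), reproducing the contrast in which the
downstream A-rich element is present at control-style PACs and absent at
stress-induced ones.

# Antisense and enrichment

Antisense PAC enrichment per treatment versus control is a right-sided Fisher
exact test on the 2x2 table of [antisense, non-antisense] x [treatment,
control] PAC counts — the unit is PACs, not reads. The p-value is the
hypergeometric upper tail (`fisher_right_p()`, verified in the tests against
a term-by-term tail-sum oracle and `fisher.test`).

Functional enrichment is the standard hypergeometric over-representation
test per term, corrected across terms by Benjamini–Hochberg ("FDR" is read
as the BH step-up; Hochberg's FWER procedure is available via
`method = "hochberg"`). The enrichment ratio is `k / K` (query genes in the
pathway over all pathway genes). The default universe is all genes with at
least one PAC — an expression-matched background is the defensible default
when none is stated. No GO-graph propagation is performed; annotation tables
are user-supplied or synthetic.

# The synthetic generator

`sim_config()` fixes the study conditions; `generate_genome()` /
`generate_reads()` / `simulate_dataset()` realize them deterministically
(same seed, byte-identical FASTA/GFF3/FASTQ/truth outputs). Defaults, chosen
once for realism at desk scale:

* 200 genes on both strands with 5'UTR (100–200 nt), codon-multiple CDS
  (300–900 nt, ATG...TAA, GT..AG introns, 0–2 per gene), and 3'UTRs of
  320–450 nt — long enough that up to three planted PACs per 3'UTR
  (probabilities 0.35/0.45/0.20) are separated by more than the 100-nt
  cross-library merge radius, otherwise planted sites would be unresolvable
  by the method's own definition;
* three conditions, control first (`CK`, `HT`, `LT`), ~100 reads per gene per
  condition (Poisson), read length 100 nt, polyA tails truncated-normal
  (mean 35, sd 12, min 8 — the minimum matches the 8-A anchor rule, so every
  clean tail is anchorable), substitution noise 0.005 per base (no indels,
  so exact toy mapping stays meaningful and tail errors exercise the
  2-non-A clip rule);
* per gene, two-PAC usage is 0.7/0.3 with the dominant end chosen at random;
  30% of multi-PAC genes shift per treatment by moving 0.4 of proximal usage
  to the other end (0.7/0.3 -> 0.3/0.7), so planted shifts have D = 0.4 and a
  planted distance equal to the inter-PAC spacing;
* a minority of genes carry one extra non-canonical site (CDS 4%, 5'UTR 2%,
  intron 2%) or an antisense site (10% of genes expressed under treatments,
  half of those also active in control — i.e. 5%/10% antisense fractions);
  extra sites take a 0.1 usage slice, sense usage rescales, so the *sense*
  conditional distribution is unchanged and no spurious shift is planted;
* sequence signals at every site: `AATAAA` at start offset -25 (within the
  canonical 16–26 nt upstream NUE region), `AAAAAA` at +5..+10 downstream,
  and a fixed `T, C` at offsets -2..-1 with `A` at 0 — the C-before-the-A
  spike seen at real plant cleavage sites. The guard also pins the trimmer:
  the cleavage-adjacent A joins the tail run and the clip stops
  deterministically at the `C`, so called positions sit one base 5' of the
  planted base (well within the ±5 nt recovery tolerance, and cancelling in
  distances). `downstream_motif_mode = "control_only"` omits the downstream
  element at treatment-dominant PACs of shifted genes, producing the
  heat-like fixture;
* cleavage micro-heterogeneity of -2..+2 nt (probabilities .1/.2/.4/.2/.1)
  around each planted site, so each PAC has several member sites and the
  "single polyA site" APA filter stays meaningful.

What the generator does *not* emulate — PCR duplicates, adapters, quality
decay, internal priming from genomic A-rich stretches, indels, expression
dispersion beyond Poisson — bounds what green tests mean: they validate the
algorithmic pipeline against its own stated rules and planted truth, not
performance on real libraries.

# Numerical and degenerate-input choices

* TPM requires `total > 0`; RPKM requires positive gene lengths; empty
  queries/universes and unknown cluster modes are errors; unknown
  chromosomes categorize as intergenic with a warning.
* Representative-site ties break to the most 3' position; category ties at
  equal priority break to the lexicographically first gene.
* The KS exact path enumerates all `choose(n, n_t)` splits only for pooled
  support of at most 20 reads.
* The toy mapper seeds with up to three non-overlapping 24-mers per
  orientation, verifies candidates by substitution count (budget 2,
  mirroring the common short-read allowance), and drops reads whose best hit
  is tied at distinct loci.

# Problem sizes used in the checks

The test-suite and the acceptance script run, by the package's own choice of
desk-scale conditions: 10,000 random reads for the trimming oracle; 1,000
random instances for the clustering oracles; 1,000 unshifted genes for KS
calibration; 100 replicates for shift detection (usage change 0.4, 100
reads/condition) and for antisense power (2,000 PACs, 5% vs 10%); a 200-gene
end-to-end benchmark for PAC recovery (±5 nt); exhaustive 2x2 tables with
margins up to 50 for the Fisher oracle; and 200 random-query replicates for
the enrichment null.

# Known limitations

* The shift score is *a* KS statistic on usage cumulatives; other weightings
  of positional usage would give different scores for multi-PAC geometries.
* Effective sample sizes treat reads as exchangeable tags; overdispersion in
  real libraries would make the raw p < 0.01 cutoff anti-conservative.
* The toy mapper requires a single-chromosome genome and exact-ish matches;
  it is a benchmark device, not an aligner.
* Antisense testing compares detected PAC counts; it does not model
  detection sensitivity differences between libraries.
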