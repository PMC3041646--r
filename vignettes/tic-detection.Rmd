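---
title: "Detecting transcription-induced chimeras in short single-end RNA-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcription-induced chimeras in short single-end RNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticfinder)
library(data.table)
```

## The problem

A transcription-induced chimera (TIC), or readthrough fusion, arises when
RNA polymerase reads through the end of one gene into the next gene on the
same strand and the spliceosome then joins an exon of the upstream gene to
an exon of the downstream gene. The resulting transcript joins two genes
without any genomic rearrangement. Detecting TICs in short (33–75 nt)
single-end RNA-Seq reads is hard because a junction-spanning read carries
only a few bases on one side of the splice, too few for a spliced aligner
to place confidently.

`ticfinder` implements two complementary detection strategies:

1. **Targeted alignment.** Build an explicit database of artificial
   exon–exon junction sequences — every donor paired with every candidate
   downstream acceptor within a distance window — and align reads to those
   targets. Sensitivity then only requires a short overhang (8 nt) past
   the junction midpoint, at the price of enumerating candidate junctions
   up front.
2. **Split-read classification.** Consume split/spliced alignment records
   (two genomic segments per read) and classify each junction by geometry
   into intragenic, readthrough, long-range, scrambled, inversion or
   translocation, including readthroughs with a novel intervening exon
   (TICIEs).

Downstream, the package assembles each called chimera, predicts its coding
region and nonsense-mediated-decay (NMD) status, compares preserved
protein domains, and summarises expression (RPKM) and readthrough splicing
efficiency.

## The targeted-alignment model

**Junction targets.** Donor and acceptor splice sites are catalogued from
the annotation: one donor per internal exon end, one acceptor per internal
exon start, deduplicated across isoforms with merged exon labels
(`e4/5` = fourth exon of five). Three target sets are built:

* *readthrough (TIC) targets*: every donor × acceptor pair on the same
  chromosome and strand, acceptor strictly downstream, within
  `max_distance` (default 200,000 bp), sharing no transcript — 80 nt of
  spliced transcript on each side of the junction (160 nt total);
* *intragenic targets*: all exon pairs within each transcript, regardless
  of distance, as a competing alignment universe for ordinary and
  exon-skipping splices;
* *shifted controls*: each readthrough target with the bases at distances
  6–10 from the junction deleted on both sides. A genuine junction read
  with a ≥6 nt overhang cannot fit a control without several mismatches,
  so the control set behaves as a null; running the identical pipeline
  against it yields the false-discovery-rate numerator.

The 80-nt flanks follow the *spliced transcript* (crossing exon
boundaries) rather than the genome; where several isoforms share a site,
the isoform giving the longest flank is used, ties broken by accession.
This maximises alignable context and is deterministic. Whether flanks
should instead stop at the terminal exon boundary is a genuinely open
choice; transcript-following flanks are strictly more permissive and any
alignment they admit is still junction-spanning.

**Aligner.** Reads are placed by exact k-mer seeding (k = 12) and ungapped
full-length extension. Seeds are taken at `max_mismatches + 1` disjoint
windows of the read (the pigeonhole principle guarantees every placement
within the mismatch budget leaves one window exact, so the candidate set
equals that of trying every k-mer); short reads fall back to all k-mer
positions. A read supports a junction only with a **unique** (across
junctions, after collapsing duplicate-coordinate targets), **≤1-mismatch**,
indel-free, full-length alignment that crosses the junction. N bases never
match. Ties between junctions are discarded as multi-mapped — the
conservative choice when two junction contexts explain a read equally
well.

**Filter cascade**, in order, with per-stage attrition logged:

1. *Intragenic equivalence*: junctions whose donor and acceptor gene sets
   intersect merely join two isoforms of one gene; dropped.
2. *Intragenic preference*: a readthrough alignment is dropped when any
   intragenic target admits the same read with as few mismatches (ties
   dropped).
3. *Overhang support*: minimum overhang ≥ 8 nt for readthrough and
   control targets (11 nt is used when reporting intragenic splicing).
4. *Cluster consistency* (window = 11): for each of the 11 positions on
   both sides of the junction, at least one covering read must match the
   target there; additionally, any covered position where *every*
   covering read mismatches (a consistent mismatch) vetoes the cluster.
   For a single-read cluster this reduces to an error-free read with
   both overhangs ≥ 11; sequencing errors are accommodated only when
   another read covers the same position cleanly.
5. *Homology*: (a) the junction fragment (longest observed left overhang
   + longest right overhang) locally aligned to any transcript of either
   component gene covering ≥ 90% of the fragment, or (b) any 5'-gene vs
   3'-gene transcript alignment with ≥ 40 matches inside a 50-column
   window, rejects the candidate — this is what removes paralogous gene
   pairs (~92% identity comfortably exceeds 40/50). Local alignment uses
   match +1, mismatch −1, gap open −2, gap extend −1; these scores are
   conventional and configurable, and the 90% coverage is measured as
   aligned (match or mismatch) fragment columns over fragment length.

Events are reported one per junction with gene pair, exon labels, splice
and intergenic distances, read/sample support, the (n−1)→+2 flag (donor
at the penultimate exon, acceptor at the second exon — the dominant
readthrough geometry), and isoform groups over gene pairs with the shared
splice site annotated. `estimate_fdr(n_control, n_real)` renders the
control-arm FDR as a percentage to one decimal (e.g. 5 and 339 give
1.5%).

## The split-read classifier

Records enter as a 10-column table (read, sample, and two genomic
segments in read order); the donor is the transcription-direction end of
segment A, the acceptor the start of segment B. Categories are assigned
in a fixed decision order so the six labels are mutually exclusive and
exhaustive: different chromosomes → translocation; opposite strands →
inversion; acceptor upstream of the donor → scrambled; distance >
200,000 bp → long-range; different genes → readthrough; else intragenic.
The order is a design choice (the taxonomy itself does not dictate one);
placing the geometry tests first means a record never needs gene
annotation to receive a distant-fusion label.

Distant-fusion calls require ≥ 2 supporting reads; readthrough calls are
accepted on a single read. The asymmetry is deliberate: with millions of
reads and millions of enumerable local junctions, a single spurious local
hit is rare after the filter cascade, whereas the space of arbitrary
distant pairings is vastly larger.

**TICIEs.** Within a sample, an upstream splice (known donor → novel
acceptor) is paired with a downstream splice (novel donor → known
acceptor) when the two novel sites delimit an interval of ≤ 300 bp
(the exon-length threshold) on one strand, both splices span ≤ 200,000
bp, the known sites belong to two different coding genes, and the gene
pair passes the gene-homology rule. The intervening interval is classified
by ≥1 bp overlap against the 5' gene's last exon, the 3' gene's first
exon, other exons, or none (intergenic). Pairs may come from different
reads of one sample — the per-sample reading of the pairing — and
same-read support is flagged separately.

## Coding potential and domains

A chimera is assembled by concatenating the 5' transcript's exons up to
the donor, the optional intervening exon, and the 3' transcript's exons
from the acceptor. If the 5' CDS start is retained, translation starts
there; otherwise the start is the longest ATG-initiated ORF of ≥ 30
codons (ties 5'-most). The 30-codon floor and the strict ATG requirement
are configuration, not biology settled by the data: they exist to keep
spurious micro-ORFs out of new-TSS calls. Frame classes: `full_cds`
(stop coincides with the 3' gene's original stop mapped into the
chimera), `shift_3p`, `new_tss`. Termination: `PTC` when the stop codon
begins before the last exon (an NMD substrate), else `TLE`. CDS
annotations are taken to run through the last base of the stop codon.

Domain preservation avoids re-running an HMM scan: a 5' domain is
preserved iff its amino-acid interval lies within the longest common
prefix of chimeric and original 5' proteins, a 3' domain iff within the
longest common suffix against the 3' protein; junction-spanning codons
belong to neither. PTC chimeras preserve no 3' domains. Statuses are ND
(no original domains), Null, Subset, Cover. Externally computed domain
tables for chimeric proteins can be supplied instead where an HMM-based
reproduction is wanted.

## Expression

RPKM = exonic reads / (merged exonic kb × library size in millions). A
read overlapping two genes counts toward both by default (configurable to
fractional). Readthrough splice expression is proxied by
junction-supporting reads per million — a sequencing-based stand-in for
the qRT-PCR measurements such figures are usually built on — and
splicing efficiency is that proxy divided by the 5' gene's expression,
reported on a log scale because it spans orders of magnitude across
events.

## The simulator and what passing tests mean

`sim_config()` → `generate_genome()` → `plant_events()` →
`assign_expression()` → `simulate_reads()` produces a toy genome,
annotation, truth manifest, reads and split records, all deterministic
under the seed (the RNG state of the session is saved and restored).
Defaults encode the validated study conditions: read lengths 33/50/75 nt,
1% substitution error, exponential intergenic spacing, log-normal
expression, 54% weight on the (n−1)→+2 splice pattern, an 11%
multiple-isoform fraction, readthrough intensity = efficiency × 5'-gene
intensity (the leakage model), 14-nt anchors for split-record emission
(the detectability threshold of split-read aligners on short reads), and
decoy paralog pairs at 92% identity that the homology filter must reject.

Test problem sizes are the package's validation choices: recovery runs
use ~50 genes with 20 planted readthroughs at read length 50; the read
depth is not fixed but derived analytically so that every planted event
expects at least five error-free junction reads with both overhangs past
the 11-nt consistency window — comfortably above the minimum coverage
(λ ≥ 3) at which recovery is demanded, so that a failure indicates a
defect rather than sampling noise. Oracle suites compare the seeded
aligner against an all-offsets scan (10,000 reads), junction enumeration
against an O(sites²) brute force, and chimera translation against a naive
codon-by-codon translator (1,000 chimeras). Efficiency recovery uses 10⁶
reads over planted efficiencies 10⁻⁴–10⁻².

The simulator emulates the *structure* of real data, not its full
messiness: uniform read starts (no coverage bias), i.i.d. substitutions
(no quality decay or indels), clean annotations, no PCR duplicates or
library artifacts, and split records emitted by construction rather than
by a real spliced aligner. Passing tests therefore demonstrate that the
algorithms are implemented correctly and are well-calibrated under their
stated model; they do not certify sensitivity or FDR on real libraries,
where alignability, paralogy and artifact structure are harsher.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout, the R/Bioconductor
  convention; all reports are 1-based.
* Donor position is the last exonic base before the intron, acceptor the
  first after; splice distance is the absolute difference of the two.
* Flanks shorter than requested (terminal exons) truncate with a flag,
  not an error; control construction skips sides under 10 nt with a
  warning.
* Gene-skipping donor–acceptor pairs are generated (the pairing rule is
  purely distance- and transcript-based); `strict_adjacency = TRUE`
  restricts to pairs with no annotated gene wholly between them.
* Empty inputs yield empty, well-formed outputs; single-exon transcripts
  contribute no splice sites and hence cannot participate in readthrough
  targets.
* Reads shorter than the seed are rejected as `no_hit`; a seed longer
  than half the shortest read triggers a warning since the 1-mismatch
  guarantee no longer holds.
* Translation that runs off the transcript end without a stop is
  classified TLE (termination cannot precede the last exon) and flagged
  by an empty stop position.

## A worked example

```{r example}
cfg <- sim_config(seed = 7, n_genes = 12, n_tic = 2, depth = 20000,
                  tic_efficiency = 0.3)
sim <- assign_expression(plant_events(generate_genome(cfg)))
reads <- simulate_reads(sim)
res <- run_targeted(sim$genome, sim$txs, reads$reads)
res
summary(res)
coding <- run_coding(res$events, sim$txs, sim$genome)
coding[, .(gene5, gene3, frame_class, termination_class, protein_aa)]
```

## Known limitations

* The targeted junction database grows with the square of local site
  density; genome-scale runs against a mammalian annotation need the
  200-kb window to stay tractable and are outside the test envelope.
* Only substitution errors are modelled and accepted (≤1 per alignment);
  indel-tolerant alignment is out of scope.
* Single-end logic throughout; read pairing is not used.
* Converging/diverging opposite-strand local fusions are not enumerated
  as targets (the classifier will still label such records inversions).
* The consistency filter's "consistent mismatch" veto is the strict
  all-covering-reads reading; the looser "same base in ≥2 reads" reading
  would admit slightly more singleton clusters with errors.
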