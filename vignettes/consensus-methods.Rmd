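---
title: "Methods: consensus calling for long-read DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus calling for long-read DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeid)
```

## The problem

A DNA barcode is a short standardized amplicon (COI, ITS, rbcL, ...) used to
identify species. Nanopore and PacBio sequencers read such amplicons in one
piece but with per-read error rates in the 1–12% range, so a single read is
not a usable barcode. Given a demultiplexed FASTQ of reads from one sample,
`barcodeid` reconstructs one high-accuracy consensus sequence per amplicon
present, by exploiting the redundancy across hundreds of reads:

1. **Filter and subsample** — reads whose mean per-base error probability
   (from the phred scores, $p_i = 10^{-q_i/10}$) exceeds a threshold are
   dropped, optionally with a length window around the expected amplicon
   size; a seeded uniform subsample can cap the read count (300 is a common
   choice, as too many reads can hurt the signal-to-noise ratio).
2. **Cluster** — a greedy, quality-ordered, minimizer-based single pass
   groups reads by sequence similarity, separating amplicons from
   contaminants and junk.
3. **Draft consensus** — each sufficiently abundant cluster is collapsed to
   a draft with a from-scratch partial-order-alignment (POA) graph.
4. **Duplicate merge** — drafts that are the same amplicon on opposite
   strands (or near-identical on the same strand) are merged and their reads
   pooled.
5. **Polish** — each consensus is corrected in rounds using its own reads
   mapped back to it.
6. **Primer trimming** (optional) — degenerate primers are located within a
   window at each end and cut off; if anything was trimmed, the merge and
   polish stages run again, because primer tails can hide strand-duplicate
   relationships.

A seeded read simulator closes the loop: every claim the test suite makes is
checked on data generated in code, with known truth.

## Clustering

Reads are sorted by the expected number of correct bases
$\sum_i (1 - 10^{-q_i/10})$ (ties: longer first, then id), so the cleanest
reads found clusters. Each read's minimizers (smallest k-mer per window of
`w` consecutive k-mers) are compared against the k-mer index of each cluster
representative; the read joins the cluster with the highest shared fraction
if it reaches `shared_fraction_threshold`, else it founds a new cluster.
Representative sketches are frozen at founding, which keeps the pass
deterministic and order-independent after sorting.

Defaults are `k = 9`, `w = 10`, threshold `0.12`, calibrated to the error
regime rather than chosen for sketch sparsity. With exact k-mer matching the
probability that a k-mer of a 7%-error read is error-free is
$0.93^9 \approx 0.52$, and both the read's minimizer and the representative's
copy must be clean, so the expected shared fraction within a cluster is about
$0.52^2 \approx 0.27$ (about 125 minimizers per 700 bp read, standard error
about 0.04). Across references at 15% or more divergence the expected shared
fraction is below about 0.03. The 0.12 threshold sits more than three
standard errors below the within-cluster mean and four above the
between-cluster one. A larger `k` (13+) would push the within-cluster overlap
down toward 0.1 and shatter clusters at ONT error rates unless matching were
quality-weighted, which this simplified scheme deliberately omits. Reads are
clustered on the strand they were sequenced: reverse-complement reads form
separate clusters *by design*, because the merge stage (which exists for
exactly this reason) reunites them and pooling the reads doubles polishing
coverage.

A cluster yields a draft only if it holds **strictly more** reads than
`abundance_ratio` (default 0.10) times the number of reads that entered
clustering; the strict inequality means a cluster sitting exactly on the
boundary is dropped. "Total reads" is the post-filter, post-subsample count —
the quantity the clusters actually partition. For deliberately mixed samples
the ratio should be lowered (e.g. 0.05 for seven pooled amplicons, since each
is only ~14% of the reads).

## Partial-order alignment

The POA graph is a DAG with one base per node; node support counts the
sequences visiting it, edge weights count traversals, and virtual start/end
markers record where sequences begin and end. Sequences are added
incrementally (cluster member order, representative first) by affine-gap
dynamic programming over the topological order (match 2, mismatch −2, gap
open −4, gap extend −2; a gap of length $L$ costs $4 + 2(L-1)$). Ties prefer
match over mismatch over deletion over insertion, then the
lowest-topological-index predecessor, so builds are fully deterministic. POA
is insertion-order sensitive; no order invariance is claimed.

Two structural rules bound graph growth: a mismatch node joins the aligned
node's *column ring*, and later sequences reuse a same-base node from the
ring (or a same-base successor of the previous path node, which covers
insertions) whenever the reuse provably cannot create a cycle, checked
against the current topological order. Without fusion the graph grows by
roughly 25 nodes per noisy read and alignment cost balloons.

**Consensus objective.** A plain "heaviest path" maximizing the sum of edge
weights is biased at realistic depth: in tandem-repeat regions alignment
phase ambiguity splits read support across parallel branches, and the
maximum-sum path zig-zags through *both* halves, collecting more total
weight than the true path and inserting phantom repeat copies (we observed
+30 bp at 150× coverage, all pure insertions). The consensus therefore
maximizes the depth-penalized score $\sum_e \left(2\,w(e) - (n+1)\right)$
over start-to-end paths, where $n$ is the number of sequences in the graph:
an edge contributes positively only with strict majority support, so
sub-majority detours never pay off while any true majority bubble still
does. For unanimous inputs and for every few-sequence example this
coincides with the heaviest path. Ties prefer higher node support, then
lower topological index.

## Pairwise alignment and the identity metric

One affine-gap Gotoh aligner (same scores) serves duplicate merging, read
mapping, primer-era re-checks and accuracy evaluation. In semi-global mode
terminal gaps of either sequence are free and excluded from the alignment
length — identity is computed over aligned columns, internal gaps included,
like a BLAST-style identity over the aligned span.

One subtlety matters: under free-end-gap alignment, two *unrelated*
sequences are optimally aligned over a few lucky corner bases, whose
column-wise identity is ~1.0 — enough to break any identity-threshold rule.
The reported identity therefore divides matches by the aligned columns
*plus* the unaligned remainder of the better-covered sequence:
near-full-length overlaps (duplicate merging, mapping, evaluation — every
use in the pipeline) are unaffected, while corner artifacts drop to ~0.
Random 500 bp pairs score below 0.75 on both strands; true
reverse-complement duplicates score 1.0.

Duplicate merging aligns all drafts pairwise in their better orientation and
links pairs at identity ≥ 0.90 (the tool's standard default). Connected
components merge transitively — order-independent and idempotent, which a
pairwise-sequential rule is not. The survivor is the member with the most
supporting reads (ties: longer sequence, then id); reads from members merged
in the opposite orientation are flagged so downstream stages know their
strand.

## Polishing

Reads are mapped semi-globally to the current consensus on their better
strand; mappings below 0.60 identity are dropped (keeps 7–12%-error reads,
rejects contaminants). Each round is Racon-style *backbone-anchored voting*:
every mapped read's CIGAR casts, per draft column, a base or deletion vote,
and per junction an insertion vote carrying the inserted string. A strict
read majority changes a column; the draft casts one vote and wins ties; an
insertion is applied when more than half the reads spanning the junction
support one, using the most frequent inserted string. The draft is tiled
into windows (500 bp, 50 bp overlap); a window spanned by fewer than 3 read
segments keeps its draft sequence verbatim. Because all edits are anchored
to draft coordinates, window outputs splice exactly.

We initially re-called windows with the POA engine, but window POA inherits
the repeat phase-split behavior described above and polishing plateaus near
98.5% identity; anchored voting converges to the truth (votes at a locus are
independent across reads, so at 100–150× coverage the per-column error
probability is negligible). Two rounds are the default, with re-mapping each
round and early stopping when a round changes nothing; `polished_rounds`
records the rounds actually executed. Up to 150 reads (highest quality
first) are used per consensus, both for drafts and for polishing — beyond
that depth the accuracy gain is nil and runtime is linear in reads.

## Primer trimming and the re-run rule

Primers (IUPAC codes allowed; `U` becomes `T` on load) are searched within a
150 bp window at each end of each polished consensus, forward and
reverse-complement, by primer-global/window-local DP with unit edit costs
and IUPAC-aware matching (`N` in the consensus matches any code, so masked
bases never block detection). A hit needs at most
`ceil(0.20 × primer length)` edits — a fraction rather than a fixed count,
since universal primers vary from 18 to 30 nt. Ties prefer the 5' end,
forward strand, leftmost position. A 5' hit is cut at its end, a 3' hit at
its start; a trim that would leave fewer than 50 bases is skipped with a
warning. If any hit occurred on any consensus, duplicate merging and
polishing run again on the trimmed set: primer tails depress pairwise
identity and can hide strand duplicates, which is precisely the failure mode
the re-run repairs. Reads keep their primers during re-polishing; semi-global
mapping leaves the tails in free overhangs, and terminal insertion votes are
ignored, so trimmed primers do not creep back in.

## The simulator

`simulate_reads()` emulates the input regime the pipeline is designed for:
per read, an error rate is drawn from Normal(0.07, 0.02) truncated to
[0.005, 0.25] (a mean and sd of exactly 0 yield error-free reads for
degenerate tests); primers, when given, are attached *before* corruption so
primer detection is exercised under realistic primer errors, with ambiguity
codes resolved randomly per read; each base then independently suffers a
substitution/insertion/deletion with mix 0.4/0.3/0.3 of the read's rate; the
read is reverse-complemented with probability 0.5; and the quality string is
uniform at $q = \mathrm{round}(-10\log_{10} r)$ for the drawn rate $r$. An
optional contaminant fraction injects reads from an unrelated random
reference to exercise the abundance filter.

What it does **not** model: homopolymer-biased and context-dependent errors,
per-base quality variation within a read, chimeras, and quality
miscalibration. Passing tests therefore demonstrate the pipeline's logic
under an idealized i.i.d. error model of the right magnitude, not
performance on any particular flow cell. Two consequences are worth noting:
uniform qualities make the quality sort a coarse ordering (fine, since only
the ordering is used), and at high divergence settings the realized identity
of `mutate_reference()` exceeds $1 - d$ because optimal alignment recovers
chance matches — visible in the tests at $d = 0.5$.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data at
the scale the method targets: 700 bp amplicons, 300 reads per sample at 7%
mean error for single barcodes, seven 700 bp references at ≥ 15% pairwise
divergence with 300 reads each (2100 reads) for the mixed-sample check, 50
to 150 reads for polishing experiments. Every generator call is seeded;
`run_pipeline()` is fully determined by the input bytes, the configuration
and the seed (the only RNG consumer is subsampling), so two identical runs
produce byte-identical consensus FASTA output.

## Known limitations

* Real variants at ≥ 90% identity collapse into one consensus by design of
  the merge rule; the tool is not a haplotyper.
* The only polisher is the Racon-style voting polisher; learned, platform-
  specific error models (Medaka-class) are out of scope, and the CLI keeps a
  `--polisher` flag with the single value `racon-like` to make that
  explicit.
* Subsampling reproducibility is within this package only (its own seeded
  RNG, not seqtk's hash).
* POA drafts are insertion-order dependent; the canonical order is cluster
  member order with the representative first.
* The external-data benchmark harness runs only on locally provided files
  listed in a user manifest and skips (never fails) anything missing.
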