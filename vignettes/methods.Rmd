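---
title: "Methods: unified splice graphs, LSV posteriors, and the synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unified splice graphs, LSV posteriors, and the synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsvcompare)
```

# The problem

Matched short-read and long-read RNA-seq of the same sample describe the
same transcriptome through very different instruments. Short reads
provide deep, junction-resolved coverage but no isoform context; long
reads provide isoform context but fewer molecules, higher error rates,
and a pronounced 3' bias: polyA-anchored cDNA reads start at the 3' end
and frequently fail to reach distal splice sites. `lsvcompare` merges
both with a reference annotation into per-gene splice graphs and
computes the statistics that make the agreement — and the systematic
disagreement — measurable.

# The unified splice graph

Coordinates are 1-based inclusive throughout (the native convention of
both GTF and STAR's `SJ.out.tab`), and a junction is keyed by its intron
interval `[exon_i_end + 1, exon_{i+1}_start − 1]`. Per gene, the edge
set is the union over sources:

* annotated junctions, from the exon chains of the annotation;
* short-read junctions, counted by unique-mapping reads, supporting an
  edge only when the count reaches `short_min_reads` (default 2 — the
  minimal reading of "multiple supporting reads"; multi-mapping reads
  are ignored as the conservative choice);
* long-read junctions, contained in transcripts that survive the
  read-count filter (default ≥ 1 read, the convention for count-aware
  callers that also emit unexpressed reference models); an edge's
  long-read count is the summed count of the transcripts containing it.

Retained introns (IR) enter as a second edge kind on the same interval
key: from the short-read IR table (any reported event counts as short
support, because that table already carries a caller's filtered calls —
thresholding it a second time would double-filter), and from long reads
whenever a transcript exon fully spans — both flanking splice sites
strictly inside the exon — an intron annotated or observed by another
source. Partial overlap is not IR.

Exons are merged across annotation and long-read transcripts, with one
deliberate asymmetry: retained-intron interiors are subtracted from the
exon union before merging. Without this, one IR-carrying transcript exon
would bridge its flanking exons into a single node and silently delete
every LSV in the region; with it, the IR edge and the junction it
competes with attach to the same reference exons. Alternative 5'/3'
splice sites internal to a merged exon are intentionally *not* split
out: edges are attached to a reference exon by containment of their
exon-proximal boundary, so alternative-site junctions join the same LSV
as their annotated neighbours, which is the intended semantics of a
local splicing variation.

Undetermined-strand short-read junctions (STAR strand code 0) are
retained and matched to stranded gene models by coordinates at build
time. Long-read transcripts are reassigned to the annotated gene with
maximal exonic overlap on the same strand (ties toward the smaller
gene identifier) because each caller's own gene labels are not
comparable across tools; transcripts overlapping no gene keep their own
label and form long-read-only genes.

# Classification

Each detected edge falls into one of six categories by its support
subset; annotation-only edges are kept in the graph but excluded from
all detected-element statistics. Unannotated junctions are
NOVEL_COMBINATION when donor and acceptor are both individually
annotated (strand-aware: the donor is the intron start on `+`, the
intron end on `−`) but the pair is not; otherwise NOVEL_SPLICE_SITE.
Long-read novel splice sites are further typed ALT_5SS / ALT_3SS /
MIXED / IR / NEW_EXON. The taxonomy treats these as disjoint but does
not define an order for overlapping geometries, so the package fixes the
precedence IR > NEW_EXON > ALT/MIXED; NEW_EXON requires a transcript
exon strictly inside an annotated intron with both boundaries
unannotated, and a junction shared by several transcripts is classified
once, by coordinates, counting any containing transcript's geometry.

Long-read transcripts are placed in a seven-class Venn over
{novel combination, novel splice site, pTSS/pTES}. pTSS (pTES) is true
when the strand-aware 5' (3') terminal boundary matches no annotated
TSS (TES) within `boundary_window` nt; the default window is 0 (exact)
because no tolerance is prescribed for this comparison, and it is
configurable for sensitivity analyses. The class containing only
pTSS/pTES is VII and is flagged excluded-from-comparison, since
short-read splicing callers cannot call transcript ends at all. The
assignment of Roman numerals to the remaining subsets is this package's
own fixed convention (I = novel combination only, II = novel splice
site only, III = both, IV/V = each with pTSS/pTES, VI = all three).

# PSI quantification

For an LSV with J elements and per-element read counts $r_j$, reads are
modelled binomially with inclusion $\Psi_j$ and the prior
$\Psi_j \sim \mathrm{Beta}(1/J,\, 1-1/J)$ — the J-way generalisation of
a Jeffreys-type prior that favours extreme inclusion values. Conjugacy
gives

$$\Psi_j \mid r \sim \mathrm{Beta}\!\left(\tfrac1J + r_j,\;
  1 - \tfrac1J + \sum_{j' \neq j} r_{j'}\right),$$

with posterior mean $(1/J + r_j)/(1 + \sum_j r_j)$; the means sum to 1
in closed form, which the package asserts to $10^{-9}$ on every
quantified LSV. With $r = 0$ the prior (mean $1/J$) is returned. The
same machinery is applied to both long-read counts (transcript-count
sums per element — what long-read callers emit) and short-read counts;
a bootstrap-based short-read stack model is out of scope here, and
using one shared posterior keeps the two technologies directly
comparable. This is a deliberate simplification.

Supporting rules: an LSV is *quantifiable* for a source when its
elements total at least `min_reads` (default 10) reads; a junction or
intron quantified in several LSVs reports its lowest posterior-mean PSI
(the conservative choice); IR PSI additionally requires the containing
LSV to pass the same 10-read filter.

The 3'-distance of an LSV is the spliced (exonic) distance from the
LSV-side boundary of its reference exon to the transcript 3' end,
minimised over the annotated transcripts containing that boundary.
Spliced rather than genomic distance is used because read length
operates in transcript space, and annotated transcripts define the 3'
ends because the long-read models are themselves 3'-truncated — both
points are open choices that the package fixes and exposes.

# Fuzzy splice-site matching

Long-read splice-site calls can be shifted by a few nucleotides.
Matching is per-site and directional: a long-read site not exactly
matching a short-read site is matched against short-read sites within
±window nt (nearest first, ties toward the smaller coordinate,
many-to-one allowed); a site still unmatched and not itself annotated
is then compared against annotated sites. Only long-read sites move.
Matched sites snap to their target; edges that come to share an
interval merge (supports unioned, long counts summed), and annotation
support is re-evaluated against the annotated junction set but never
removed. Category counts are tabulated over the *original* elements
(each pre-match edge takes the category of its post-merge edge), so the
total is conserved at every window, ALL and BOTH_DENOVO can only grow,
and LONG_ONLY can only shrink. Two numerical details make the procedure
idempotent: every snapped coordinate is a fixed point, because
annotation fallback targets are restricted to annotated sites with no
short-read site within the window. Window 0 reproduces exact matching;
sweeps run each window independently, not cumulatively.

# The synthetic study conditions

`sim_config()` defines the generator's defaults; they are the package's
study conditions and its tests are statements about data generated
under them.

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | genes per fixture |
| `exons_per_gene` | 6–15 | chain length; with 100–400 nt exons, spliced transcripts reach beyond 2.5 kb so the distal 3'-distance bin is populated |
| `intron_len` | 200–2500 nt | genomic intron lengths |
| `expr_meanlog`, `expr_sdlog` | log 12, 0.7 | log-normal isoform expression |
| `short_mu`, `short_size` | 40, 5 | negative-binomial junction counts, mean scaled by true inclusion |
| `long_depth` | 1 | isoform long reads ~ Poisson(depth × expression × weight) |
| `full_length_prob` | 0.05 | mass of full-length reads; the ONT-like regime where only a few percent of reads span ≥ 3 kb |
| `trunc_scale` | 1000 nt | exponential truncation from the TES in spliced nt; `Inf` disables |
| `p_skip_isoform` | 0.8 | second annotated isoform (exon skip) — the LSV backbone; its true PSI is drawn from the extreme-favouring 50/50 mixture Beta(0.2, 0.8)/Beta(0.8, 0.2), mirroring the prior's shape |
| novelty rates | 0.05–0.5 | per-gene injection of ALT_5SS/ALT_3SS/MIXED (0.08/0.08/0.05), novel combination (0.1), new exon (0.08), long IR (0.5), short IR (0.1), annotated IR isoform (0.05), short-only de novo junction (0.25, of which 90% novel splice site), pTES shift (0.08) |
| `long_dropout_rate` | 0 | optional hiding of junctions from long reads; emitted chains split at hidden junctions into fragments, so the rate maps one-to-one to the per-junction missed fraction |

Truncated reads are grouped by the set of junctions they cover and
emitted as suffix transcript models snapped to exon boundaries — the
partial models real callers produce — which is also what generates
pTSS-only (class VII) transcripts naturally. Ground-truth labels are
derived from the *realised* draws by direct set logic over the emitted
structures (annotated site/junction sets, SJ counts against the
detection threshold, emitted chains), so labels are consistent with the
files by construction; identical seeds give byte-identical files.

Under these defaults the generator reproduces the qualitative phenomena
the comparison is designed to measure: short reads detect more
junctions than long reads; long-read junction coverage falls with
spliced 3'-distance (negative Spearman correlation, and distance-binned
non-quantifiable fractions that increase monotonically); long reads
report several-fold more IR events than short reads; and roughly
19 of 20 simulated reads are shorter than 3 kb. What the generator does
*not* emulate: sequencing errors and alignment artifacts (splice-site
calls are exact up to the injected shifts), multi-gene loci and
overlapping genes, expression-linked biases other than 3' truncation,
and caller-specific model-selection behaviour. Tests passing on these
conditions therefore validate the pipeline's logic and statistics, not
any specific caller's accuracy on real reads.

# Numerical and degenerate-input choices

* Ties in fuzzy matching break toward the smaller genomic coordinate;
  ties in gene assignment toward the smaller gene identifier.
* Empty GTFs yield empty sets with a warning; malformed GTF lines and
  duplicate junction/intron keys are errors naming the offence.
* A gene with no annotated transcripts sets pTSS/pTES to TRUE with a
  warning; an LSV whose reference boundary lies in no annotated
  transcript has undefined 3'-distance and is excluded from
  distance-binned tables; empty report bins are emitted as missing
  values, not zeros.
* All tables are written with deterministic column order and 6
  significant digits; runs are deterministic functions of inputs and
  configuration (the manifest contains no timestamps), which the test
  suite checks byte-for-byte.

# Problem sizes used by the tests

The default fixture is 200 genes (roughly 2,000 detected junctions,
500 LSVs and 1,300 long-read transcript models); the brute-force
category oracle runs on over 1,000 edges; distance oracles enumerate
exonic positions on 100 random genes; determinism is checked on
30-gene runs. These sizes were chosen as the smallest at which the
statistical checks (Spearman tests, binned monotonicity) are stable
across seeds.

# Known limitations

* One long-read source per run; comparing PacBio and ONT means running
  twice and joining tables.
* The positional-coverage criterion of short-read junction calling
  (reads at multiple positions) cannot be reproduced from `SJ.out.tab`,
  which lacks per-position detail; the count threshold stands in for it.
* Short-read PSI uses the same beta-binomial posterior as long reads
  rather than a bootstrap model (see above).
* Delta-PSI between conditions, alignment, and isoform-level abundance
  estimation are out of scope.
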