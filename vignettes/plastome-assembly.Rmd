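---
title: "Assembling and comparing chloroplast genomes from total-DNA mate-pair reads"
author: "plastomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and comparing chloroplast genomes from total-DNA mate-pair reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

## The problem

Chloroplast genomes (plastomes) are small (120–220 kb), circular, and
present in hundreds of copies per cell, so unfractionated total leaf DNA is
already strongly enriched for plastid sequence. `plastomics` implements a
complete pipeline for exploiting that enrichment: short mate-pair reads
from total DNA are quality-filtered, baited against the plastome of a
related species, assembled de novo, corrected into collinearity with the
reference, finished with long reads, and completed by reconstructing the
second inverted-repeat copy. A comparative layer computes pairwise
divergence statistics (substitution rate, transition/transversion ratio,
INDEL ratio) and a maximum-parsimony phylogeny with bootstrap support.

Flowering-plant plastomes are quadripartite: a large single-copy region
(LSC, around 90 kb), a small single-copy region (SSC, around 10 kb), and
two identical inverted repeats (IRa/IRb, around 31 kb each) with IRb the
reverse complement of IRa. Because the two repeats are identical, assembly
is performed on the single-copy core LSC+IRa+SSC, and IRb is appended at
the end — exactly what `add_inverted_repeat()` does.

A synthetic-data module generates every input the pipeline needs —
plastome models, evolved relatives with a controlled mutation log, and
total-DNA mate-pair libraries — so the whole pipeline is testable without
any external download.

## The simulation model

`simulate_plastome()` draws uniform random DNA in the canonical 90/31/10 kb
proportions (scaled by one `size_factor`) and places non-overlapping gene
features across LSC, IRa and SSC. `simulate_total_dna_library()` then draws
read pairs from three compartments — chloroplast (circular), a nuclear
decoy and a mitochondrial decoy — with probability proportional to copy
number times length; the default of 100 chloroplast copies per nuclear
copy reproduces the enrichment seen in duckweed leaf tissue. Tags are
50 nt, inserts ~Normal(1500, 150) nt, pairs outward-facing (the mate-pair
convention of ligation-circularisation libraries; `orientation = "inward"`
is available). Base qualities follow
`clamp(Normal(mu = 28, sd = 6), 2, 40)` with a 5% fraction of bad reads at
`mu = 12`, so the QV-20 filter has realistic work to do. Sequencing errors
are uniform substitutions at a configurable per-base rate.

What the simulator deliberately does **not** emulate: platform-specific
(colorspace) encodings, empirically fitted error profiles, heteroplasmy,
and the long mononucleotide runs and low-complexity tracts that interrupt
contigs in real plastomes (uniform random DNA contains almost none). A
passing test suite therefore demonstrates algorithmic correctness of the
pipeline, not robustness to every artefact of real sequencing data.

### Evolution with an exact event log

`evolve_genome()` mutates the single-copy core and returns, alongside the
derived genome, a `MutationEventLog` and the gapped truth alignment the
events imply. INDEL events are drawn per ancestral site at `indel_rate`
(insertions and deletions equally likely); lengths follow a truncated
geometric distribution with mean 5 nt by default — plastome intergenic
indels are predominantly short — and `indel_rate_for_ratio()` back-solves
the event rate for a target INDEL ratio through
`ratio = rm / (1 + rm/2)` (with `m` the mean event length), since
insertions add alignment columns while deletions add gap characters only.

The substitution count is drawn as `Binomial(alignment columns,
substitution_rate)` and placed uniformly on non-gap columns. This realises
the definition of the substitution rate — expected substitutions *per
aligned site* — exactly; a per-ancestor-site draw would be biased by the
ratio of ancestor length to alignment length (about 4% at an INDEL ratio
of 0.073), which matters when parameter recovery is checked at binomial
precision. Each substitution is a transition with probability
`R_target / (1 + R_target)`, so the expected si/sv ratio equals
`R_target`; with `R_target = 0.5` all six unordered substitution types are
equally likely, the 1:2 null of two transition pairs against four
transversion pairs. Substitutions inside gene features can be thinned with
`coding_rate_multiplier` to mimic purifying selection.

Two smaller conventions keep the log exact: deletions are logged as merged
runs, and an insertion whose anchor falls strictly inside a deleted run is
suppressed, so replaying the log on the ancestor by plain string surgery
reproduces the derived sequence without coordinate ambiguity. The
suppression removes a small fraction of insertions (roughly the deleted
fraction of sites, ~4% at the strongest preset), a second-order effect on
the realized INDEL ratio that stays well inside the tolerance used
anywhere in the package.

`evolution_preset()` bundles the whole-genome divergence regimes observed
between duckweed plastomes: substitution rate 0.05 with R 0.7 and INDEL
ratio 0.073 for an intra-tribe pair, 0.04/0.6/0.061 for the second
intra-tribe pair, and 0.07/0.6/0.089 for an inter-tribe pair.

## The assembly pipeline

```{r pipeline, eval = FALSE}
ref <- simulate_plastome(size_factor = 0.1, gene_count = 20, seed = 1)
tgt <- evolve_genome(ref, evolution_preset("intra-tribe", seed = 2))
lib <- simulate_total_dna_library(tgt$genome, n_pairs = 32000, seed = 3)

fq  <- filter_mate_pairs(lib)                              # step 1
sel <- select_anchored_pairs(fq$library, plastome_core(ref))  # step 2
ap  <- assembly_params(min_pair_count = 5)
ctg <- build_contigs(c(sel$library$tagF, sel$library$tagR), ap)  # step 3
sc  <- scaffold_contigs(ctg, sel$library, ap)
pm  <- order_against_reference(sc, ctg, plastome_core(ref))   # step 5
it  <- reiterate(fq$library, pm, plastome_core(ref), ap)      # step 4
fin <- simulate_finishing_reads(plastome_sequence(tgt$genome),
                                circular = TRUE)
cl  <- close_gaps(it$pseudomolecule, fin)                     # steps 6-7
full <- add_inverted_repeat(cl$sequence, reference = ref)     # IR rebuild
```

**Quality filtering** (`filter_mate_pairs()`). Tags are truncated to their
40 nt prefix and kept when the mean QV *on the truncated prefix* strictly
exceeds 20; a pair survives only if both mates pass, because scaffolding
needs intact pairs. Prefix truncation (rather than a best-window search)
keeps the operation deterministic, and computing the mean after truncation
resolves the order ambiguity in favour of the bases actually used
downstream. Means are not rounded before comparison.

**Read selection** (`select_anchored_pairs()`). A pair is retained when at
least one tag maps end-to-end to the reference with at most
`floor(0.1 × length)` mismatches. The mapper indexes exact seeds and
verifies candidates by ungapped comparison; seeding partitions each tag
into `max_mismatches + 1` non-overlapping seeds of length
`min(seed_k, floor(L/(max_mismatches+1)))` (8 nt for 40-nt tags at the
default 10%), so by the pigeonhole principle any admissible placement
contains an exact seed and the search provably agrees with a brute-force
scan of every offset and strand. Ungapped extension is intentional: with
40 nt tags, reads containing indels are simply lost to mapping, the
behaviour of a default-parameter short-read aligner. Reported positions
are 1-based. For coverage profiles, a read with several equally valid
placements (the inverted repeats) is assigned one placement uniformly at
random under a seed, conserving total placements while the repeat copies
share coverage.

**Contig assembly** (`build_contigs()`). A de Bruijn graph over canonical
k-mers (lexicographic minimum of k-mer and reverse complement; k odd so no
k-mer is its own reverse complement) with hash length 19 and coverage
cutoff 11 — the parameter pair used for high-coverage organelle assemblies
— emits maximal non-branching paths. Dead-end tips shorter than 2k are
clipped and simple bubbles are popped in favour of the higher-coverage
path; bubble parallelism is judged between reverse-complement equivalence
classes of the sequence, because in a collapsed circular plastome graph a
unitig can legitimately run from a node to its own reverse complement and
thereby share endpoints with its RC twin without being a bubble. The
coverage cutoff is applied at the k-mer level and contig mean coverage is
at least the cutoff by construction. Pairs are not used inside contig
building, which keeps contig assembly and scaffolding independently
testable. On a typical simulated plastome the contig graph collapses to
exactly three contigs — LSC, IR (at doubled coverage) and SSC.

**Scaffolding** (`scaffold_contigs()`). Each pair whose two tags map
uniquely to different contigs votes for an oriented junction; junctions
with at least `min_pair_count` votes are accepted (default 120 as used for
deep real libraries; scale down — for example to 5 — for small simulated
ones). Gaps are estimated as insert mean minus observed flanking
distances, floored at zero. Conflicts are resolved greedily by support
(ties to the smaller contig id) and junctions that would close a cycle are
dropped — in the greedy order the dropped edge is the weakest in its
cycle.

**Reference-collinear correction** (`order_against_reference()`). Contigs
are anchored by maximal unique 31-mer matches merged into exact blocks and
chained by longest increasing subsequence. Scaffolds whose neighbouring
contigs imply a strand flip or a reference jump above 5 kb are split at
the gap between them; all pieces are ordered and oriented by anchored
reference midpoints and concatenated with exactly one N per junction.
Contigs without a confident anchor (fewer than 62 anchored bases, two full
anchor k-mers) are reported as unplaced rather than guessed. `reiterate()`
then re-runs selection against the pseudomolecule — recovering reads that
diverge from the original reference — and reassembles and reorders.

**Gap closure** (`close_gaps()`). Long finishing reads are anchored to
both flanks of each gap by exact 21-mer seeds with offset voting and
verified ungapped over at least 100 columns per flank at a mismatch rate
of at most 2%. The single N is replaced by the read segment spanning the
gap; when the two flank offsets imply a *negative* span — neighbouring de
Bruijn contigs overlap by up to k−1 bases of shared junction sequence —
the overlap is trimmed instead. Every verified overlap column is tallied
into a `DiscrepancyReport` (substitution mismatches only; a read with an
indel against the consensus fails ungapped verification and is counted as
excluded, so indel disagreements surface as excluded overlaps rather than
columns). The 100 nt minimum overlap is a declared default.

**IR reconstruction** (`add_inverted_repeat()`). The IRa boundaries are
projected from the annotated reference by anchor chaining refined with a
windowed (±300 nt) global alignment — these junctions are flanked by
assembled sequence on both sides, so the projection is exact up to local
alignment ambiguity. The terminal trim is then determined
self-consistently rather than by projection: contigs assembled from a
circular molecule legitimately run past the canonical core ends into IRb,
and by the quadripartite identity a start overhang of length t must equal
the reverse complement of IRa's first t bases (and an end overhang the
reverse complement of IRa's tail). The reference projection centres the
search and the junction identity fixes the exact cut, so target-specific
indels right at a junction cannot shift the trim. IRb is finally appended
as the reverse complement of the IRa segment.
`detect_inverted_repeat()` inverts the construction for complete genomes,
locating the repeat pair by matching k-mers between the genome and its
reverse complement; `exclude_irb()` uses it when no annotation is
available.

## Comparative statistics

`pairwise_genome_align()` aligns two collinear genomes by chaining k-mers
unique in both (default 15-mers) and closing inter-anchor segments with
affine-gap global dynamic programming. The scoring is match +1, mismatch
−1, gap open −2, gap extend −0.25. The mild gap penalties are a deliberate
estimator choice: at plastome-level divergence, nearby insertion and
deletion events otherwise get absorbed into mismatch runs whenever the gap
cost exceeds the expected mismatch cost of the merged segment, inflating
the substitution count and deflating the INDEL length; with the default
scheme the residual biases are an order of magnitude below the sampling
noise of a 140 kb comparison. Chained anchor blocks are shrunk by 5 nt per
side so their boundaries are re-optimised by the DP; equal-length segments
whose direct stacking has at most `floor(gap_open + gap_ext)` mismatches
are stacked as-is (provably optimal, since any gapped alternative pays for
two gap runs), and the rest are aligned in one batched call. On short
inputs the anchored score equals the full quadratic DP score; unanchored
stretches beyond 20 kb raise an error instead of attempting a quadratic
alignment.

`divergence_stats()` classifies every column: gap characters count toward
the INDEL length; columns with N (or any non-ACGT code, treated as N) are
excluded from substitution counts but included in the alignment length,
the pairwise-deletion convention; substitutions are unordered base pairs —
A:G and C:T are transitions (si), the four others transversions (sv) —
because ancestral state is unknown in a pairwise comparison. Derived
quantities follow the conventional formulas: substitution rate =
substitutions / alignment length (gapped columns included, which is why
published whole-plastome alignment lengths exceed the gap-free sequence
length), R = si/sv, INDEL ratio = total gap characters across both rows /
alignment length. When sv = 0 with si > 0, R is reported as `Inf`; with no
substitutions at all it is `NA`. Report rounding is two decimals for the
rate, one for R and three for the INDEL ratio, matching the usual printed
precision; unrounded values are always retained.

`exclude_irb()` removes the second repeat copy before whole-genome
comparisons (keeping it would double-count the repeat), and
`concatenate_coding()` builds the concatenated protein-coding molecule
(genes in genome order, minus-strand genes reverse-complemented) for
coding-region divergence.

## Phylogeny

`mp_search()` enumerates every unrooted binary topology (15 for five
taxa; refused above 9 taxa, where exhaustive enumeration stops being
honest) and scores each with a vectorised Fitch pass over site patterns;
gaps and N are missing data (the full state set) and never force a change.
Site-pattern compression makes the bootstrap cheap: a replicate only
reweights patterns. `bootstrap_support()` resamples columns with
replacement, repeats the exhaustive search, and counts how often each
internal bipartition of the original best tree occurs in the replicate
optimum — the strict consensus when a replicate ties — mapping supports
onto the best tree's nodes as percentages. Matrices over several genomes
are produced by `project_to_backbone()`, which aligns each genome pairwise
to a chosen backbone and projects aligned bases onto backbone coordinates
(insertions relative to the backbone are dropped; deletions become gaps).
This sidesteps full multiple alignment at the cost of ignoring variation
inside backbone-absent segments — acceptable for the highly collinear
genomes the method targets. `root_with_outgroup()` places the root on the
outgroup's pendant edge and reports the ingroup branching order from the
basal lineage to the terminal cherry.

## Problem sizes and tolerances used by the test suite

The suite exercises the statistics at the scales at which their published
counterparts were computed, scaled where full size would buy nothing:
parameter recovery runs on a ~140 kb single-copy region (the size of a
whole-plastome alignment) and is checked within three binomial standard
errors for the substitution rate (SE = sqrt(p(1−p)/n) with n the alignment
columns) and, via the delta method on the transition fraction, for R. The
realized INDEL ratio is not a per-column binomial — its variance is driven
by the event count times the second moment of the event-length
distribution, Var ≈ L·r·E[len²] — so its check uses that standard error.
The assembler oracle uses error-free 100× mate pairs from a repeat-free
20 kb source with the production hash length and cutoff and
`min_pair_count` scaled to 5; the end-to-end test runs the full pipeline
at `size_factor = 0.1` (a 16.2 kb plastome) with a 100:1
chloroplast:nuclear mixture and requires at least 99.9% identity to truth;
the phylogeny acceptance uses 200 bootstrap replicates on a simulated
five-taxon set. These sizes are the package's own choices for a
comfortable desk-scale run while keeping every estimator inside its
asymptotic regime.

## Known limitations

* The mapper is ungapped by design; indel-containing reads are lost at
  selection, as with default short-read aligner settings on 40 nt tags.
* Divergent inverted repeats are out of scope: evolution mirrors IRa into
  IRb exactly, and the assembler collapses the repeats by construction.
* `close_gaps()` verifies overlaps ungapped; finishing reads carrying
  indels against the consensus are excluded rather than realigned.
* Exhaustive parsimony search limits the phylogeny module to small taxon
  sets; heuristic tree search is deliberately not provided.
* Backbone projection discards insertions relative to the backbone, so
  phylogenetic signal inside backbone-absent regions is not used.
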