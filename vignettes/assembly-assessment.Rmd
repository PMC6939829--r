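---
title: "Assessing and comparing de novo assemblies with asmqc"
author: "asmqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and comparing de novo assemblies with asmqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
options(asmqc.verbose = FALSE)
```

# The problem

Given one sequencing dataset from a heterozygous diploid individual, many
assemblers will produce many different, individually plausible assemblies.
This package implements a set of complementary measures for choosing among
them, organised around two ideas. First, a randomly held-out *validation*
subset of reads is excluded from assembly and used only for evaluation, so
that mapping-based measures are not biased by reusing the assembly's own
data. Second, because assemblers handle heterozygous regions
inconsistently — sometimes collapsing the two haplotypes into one contig,
sometimes emitting both (a *primary contig* and a *haplotig*) — several
measures are designed around haplotype redundancy: assembly ploidy,
duplicated-gene content, and the GCICA haplotig-purging rules.

This vignette records the models, parameter choices, numerical decisions
and known limitations, in that order of importance.

# Measures and their assumptions

## Validation-read holdout

`splitReads()` assigns each read (each *pair* in paired mode, so mates are
never separated) to the validation set by an independent Bernoulli draw
with probability `validation_fraction` under a fixed seed. A Bernoulli
draw rather than an exact-count sample keeps the split a one-pass
streaming operation and is faithful to "randomly assigning" semantics;
the realised share therefore fluctuates binomially around the requested
fraction. The fraction is a free parameter (defaulting to the common ~10%
choice) because published holdouts differ between read types.

## Contiguity statistics

`contigStats()` computes N50 by the descending-length cumulative sum
first reaching *at least* half the assembled bases (>=, not >); L50 is the
number of contigs at that crossing. The GC percentage is computed over
A/C/G/T bases only while the N percentage is over all bases — the only
reading under which both columns of a standard assembly table are
consistent simultaneously. Empty assemblies are an error, not a row of
zeros.

## K-mer genome size

`countKmers()` builds an exact canonical k-mer multiplicity histogram
(lexicographic minimum of a k-mer and its reverse complement; k-mers
containing N skipped; multiplicities above `cap` accumulated in the cap
bin). Exact hashing rather than a probabilistic sketch was a deliberate
choice: the acceptance tests check the estimator against arithmetic
oracles, which requires deterministic counts.

`estimateGenomeSize()` uses the classical mass-over-peak rule
G = Σ~m≥c~ m·n(m) / λ with three numerical decisions:

* **Error cutoff c**: the first local minimum scanning up from
  multiplicity 1. If the spectrum does not descend at all at the origin
  (error-free reads), the cutoff is 1; if no valley exists the function
  refuses to guess and asks for an explicit override.
* **Homozygous peak λ**: the multiplicity maximising m·n(m) at or above
  the cutoff. Real spectra are lumpy well beyond Poisson noise because
  neighbouring k-mers share read coverage, so the arg-max is located on a
  window-5 moving average of the mass curve (ties resolve to the centre of
  the tied run), then refined to the mass-weighted centroid of the ±5
  neighbourhood. This keeps isolated spikes — including spikes at a hard
  spectrum edge — exactly where they are while stabilising the peak on
  noisy spectra.
* **Diploid disambiguation**: when the mass peak p has a companion peak
  near 2p (within [1.8p, 2.2p]) carrying at least 20% of its mass, the
  spectrum is read as heterozygous-dominated and 2p is taken as λ. This is
  the standard diploid spectrum shape; without the check, a highly
  heterozygous genome would be sized against the het peak and come out
  nearly double.

Defaults are k = 21 and cap = 1000. k = 21 keeps memory at desk scale and
the estimator is k-robust on synthetic data; the cap matches the usual
spectrum cap of k-mer counting tools. Mass above the cap is *included at
cap multiplicity*, which systematically underestimates repeat-rich
genomes — with the default simulator (10% of the genome in a dispersed
repeat family whose copies sit far above the cap) the recovery error is a
consistent -7 to -10%. This is documented, not corrected: full mixture
modelling of the spectrum is out of scope.

## Assembly ploidy

`assemblyPloidy()` is assembly length over haploid genome size, reported
raw and rounded half-up to two decimals (the precision of published
tables; note that R's own `round()` rounds half to even, so the package
carries a small half-up helper). The genome size is always an explicit
argument: choosing between conflicting estimators is a judgment call that
the toolkit refuses to make silently.

## The anchor-chain aligner

All contig-scale alignment (contig-vs-contig, marker mapping,
whole-assembly similarity, read bridging) uses one internal aligner:

1. **Seeding**: exact-match anchors of `seed_k` = 15 bases, both strands,
   found through a hash index of target k-mers; seeds occurring more than
   `max_occ` = 200 times in the target are skipped as repeat noise.
   Diagonal runs of matches are merged into maximal anchors.
2. **Chaining**: a gap-penalised dynamic program over anchors sorted by
   query position, with a bounded look-back window (64 predecessors) and
   penalties `gap_open` + `gap_ext`·|Δdiagonal| plus a mild cost on the
   bridged distance; gaps above `max_gap` = 2000 bp split chains. Score
   ties break toward the lower target coordinate so outputs are
   deterministic.
3. **Gap closure**: inter-anchor gaps are closed by an own banded global
   Needleman–Wunsch (match 2, mismatch −4, linear gap −4) that emits
   explicit =/X/I/D operations; gaps of at most 400 bp get the exact full
   DP, larger ones a band of |Δlength| + `band` (default 100).

Block identity is matching columns over all alignment columns × 100.
Blocks shorter than `min_block_len` = 100 columns or below `min_identity`
(75 for assembly-vs-assembly, matching common whole-genome-similarity
practice) are discarded. Because blocks are anchor-bounded, a few bases at
the extreme sequence ends fall outside blocks; the read-mapping bridge
(`mapReads()`) additionally extends alignments to the read ends so that
error rates are computed over full reads.

E-value thresholds of database search tools are deliberately replaced by
(identity, coverage, length) triples — E-values are database-size
dependent and this aligner is not a database search. Marker mapping uses
(80%, 0.5 of the marker length, 60 bp).

## Coverage conventions

`referenceCoverage()` *merges* overlapping aligned reference intervals, so
each reference base counts once — the right convention for "how much of
assembly B does assembly A cover". `binnedCoverage()` deliberately does
**not** merge: per 1-Mb bin it sums all aligned length, so a base aligned
twice counts twice. The two conventions answer different questions
(completeness vs duplication structure) and both are exposed; tests pin
each against per-base oracles.

## GCICA

`detectPairs()` maps markers (typically conserved gene sequences) to all
contigs, then for each unordered contig pair with a shared marker
computes: the fraction of the *smaller* contig's markers also present on
the larger (strictly > 0.70 required), and the fraction of the smaller
contig's bases covered by merged alignment blocks against the larger
(≥ 0.80 required). Two readings were genuinely open:

* *Which contig's marker set anchors the 70% rule.* The containment clause
  is explicitly about the smaller contig, so its marker set anchors the
  fraction by default; `share_on = "larger"` exposes the other reading.
* *Marker multiplicity.* A marker placed twice within one contig counts
  once — the rule is about marker presence.

`purgeHaplotigs()` keeps the original human-review workflow in `"report"`
mode and automates it in `"auto"` mode behind a stricter containment
threshold (0.95): reproducibility requires an explicit criterion where the
original procedure examined alignments by eye. Removal order (descending
containment, then shared fraction, then id) resolves chains in which one
contig is "larger" in one pair and "smaller" in another; a contig already
removed is never removed again, and pairs whose larger contig is gone are
skipped with a log line. A read-depth haplotig classifier is *not*
re-implemented; `contigDepthStats()` provides a median-depth sanity check
only.

## Validation-read evaluation

`baseErrorRate()` counts primary alignments only and defines the error
rate as (mismatches + inserted bases + deleted bases) / aligned bases,
clipped bases excluded from the denominator — the semantics of standard
mapping-QC reports. Mismatch counts come from =/X CIGARs, else MD tags,
else NM minus indel bases; a record with none of these raises an
"insufficient tags" error rather than contributing a silent zero. The
companion bound `theoreticalMinError()` is tech error + h/2: a haploid
sequence cannot match both alleles, so about half of all reads mismatch at
each heterozygous site.

`detectSV()` is a deliberate simplification of full SV-caller models:
signatures are intra-alignment I/D operations ≥ `min_size` (default 50 bp,
the common caller convention; the size floor is a declared default, not an
inferred one) and split-read adjacencies (reference gap → DEL, read gap →
INS, contig change → TRA; opposite-strand segments — inversions — are not
classified). Signatures cluster greedily per (type, contig) within
`cluster_window` = 1000 bp, events report the median position/length of
their members, and only events with ≥ `min_support` = 10 distinct reads
survive. There is no breakpoint refinement and no genotyping.

## The comparison report

`assembleReport()` merges computed metrics with externally supplied
BUSCO/LAI/CGAL values (these are other tools' methods and enter as config
only). Best-marking directions: higher-better for N50, complete genes,
LAI, mapping rates and CGAL; lower-better for error rates, SV totals and
duplicated/fragmented genes; ploidy is scored by distance to a declared
target (1 for a haploid goal, 2 for diploid). Ties are marked jointly.
`rankAssemblies()` offers a Borda count over per-metric ranks, explicitly
labelled advisory: a defensible overall choice weighs the metrics with
judgment, which is why the per-metric ranks are returned alongside the
score.

# The synthetic-data generator

`simulateDiploid()` builds haplotype A as random sequence with a planted
dispersed repeat family and derives haplotype B by applying an exactly
recorded truth set: SNVs at `h_snv` (default 0.015 — the heterozygosity of
the motivating tree genome), small indels at `h_indel`, and structural
variants from an explicit spec. `simulateLongReads()` draws lognormal read
lengths (mean 12.5 kb, truncated to [1 kb, 150 kb], echoing a filtered
nanopore read set) with a per-read error rate from [0.10, 0.15] composed
40/30/30 of substitutions/insertions/deletions — a nanopore-like mix,
configurable and documented as an assumption. `simulateShortReads()`
makes 150 bp pairs at a Normal(400, 40) insert with 0.3% substitutions.
Qualities are constant (Q9 long, Q37 short): downstream modules ignore
base quality, so per-base quality realism would be decoration.
`corruptAssembly()` plants the defects the measures are designed to
expose: haplotig duplications (a diverged copy of a contig region as a new
contig), misjoins implemented as *reciprocal tail swaps* at internal
breakpoints — a plain concatenation of two whole contigs would produce no
split-read signal from true reads, whereas swapped tails are crossed by
reads at both breakpoints — and small consensus indels.

Everything is a pure function of (parameters, seed): identical inputs give
identical bytes, and the RNG state of the calling session is restored.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: chimeric reads and adapters, homopolymer-biased
nanopore errors, non-uniform coverage (GC bias, mappability), polyploid
mixtures, and genome-scale repeat complexity. Results on real data depend
on the external mapper and marker set used.

# Problem sizes in tests

The test and acceptance suites run on deliberately small instances chosen
as the package's own desk-scale conditions: 500 kb diploid genomes at 40×
for genome-size recovery (5 seeds), 8 × 12 kb contigs with 3 planted
98%-identity haplotigs for GCICA recovery (20 seeds), a 60 kb genome with
ten planted 120–300 bp SVs at 25× for the SV caller, and a 150 kb genome
at 2% heterozygosity and 15× for the error-rate check. The error-rate
tolerance combines the per-base binomial standard error with the
read-level haplotype-sampling variance (each read is entirely from one
haplotype, so the realised error rate inherits the binomial noise of the
haplotype share).

# Known limitations

* The genome-size estimator underestimates when repeat families exceed the
  multiplicity cap (see above) and cannot arbitrate between conflicting
  external estimators.
* The aligner is a desk-scale stand-in for production whole-genome
  aligners: no maximal-unique-match semantics, no spliced or protein
  alignment, no E-values. On multi-hundred-megabase assemblies a dedicated
  aligner will be faster.
* The SV caller's three classes (INS/DEL/TRA) and greedy clustering are a
  simplification; inversion and duplication calls, breakpoint refinement
  and genotyping are out of scope.
* GCICA assumes markers dense enough that true haplotig pairs share
  several; contigs with no mapped markers can never become candidates and
  are only logged.
* BUSCO, LAI and CGAL are ingested, never computed.
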