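---
title: "Profiling isomiRs with exact k-mer lookup tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling isomiRs with exact k-mer lookup tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirs)
```

## The model

A miRNA precursor arm produces a population of isoforms ("isomiRs") whose
5′ and 3′ termini vary by a few nucleotides around the database-annotated
mature sequence. `isomirs` treats isomiR identification as an exact
set-membership problem rather than an alignment problem. The central object
is a pair of precomputed lookup tables:

* the **wild-type table** keys every substring of length 18–26 nt of every
  flank-expanded precursor in the selected reference set;
* the **variant table** keys every sequence obtainable from those
  precursors by applying exactly one catalogued single-nucleotide variant,
  minus any sequence already present in the wild-type table.

Because the tables are exhaustive over their generating model, read
resolution is a deterministic exact lookup: there are no alignment scores,
no heuristics and no probabilistic tie-breaking, so a read set produces the
same profile on every run and under every input permutation, and a
templated isomiR present in the data can never be missed. The price is that
the model is closed-world — a molecule outside the enumerated universe
(e.g. an isoform of an unannotated precursor) is reported as unmapped, by
design. The tool is an annotator/quantifier, not a discovery tool.

### Assumptions

* Input reads are quality-trimmed and adapter-free; trimming is out of
  scope and a hard precondition.
* Reads are in DNA space (`T`, not `U`); sequences containing `N` are
  excluded from lookup (exact-match semantics are undefined for them) but
  kept in the totals.
* Only terminal 3′ events are modelled for non-templated additions;
  internal editing and 5′ additions are out of scope.

## Coordinates, flanks and miRNA-space

All user-visible coordinates are 1-based inclusive; any half-open
arithmetic is internal. Each precursor is expanded by `flank` nucleotides
(default **6 nt**, the value used throughout) of genomic context per side,
in precursor orientation; on the minus strand the expanded sequence is the
reverse complement of the genomic slice. The flank serves two purposes:
databases disagree about precursor boundaries (some entries are truncated
relatives of the other database's), and real isoforms overrun annotated
ends. A flank that would cross a chromosome edge is clipped with a warning
and the realised pads (`pad5`, `pad3`) are recorded so downstream
arithmetic stays exact.

**miRNA-space** is the union of the flank-expanded precursor intervals.
Exclusivity is judged against it: a k-mer all of whose genomic instances
lie inside miRNA-space is *exclusive*, otherwise *ambiguous*. Two
deliberate choices here:

* the flanks are part of miRNA-space — otherwise every 3′-extended isomiR
  reaching into a flank would be tagged ambiguous by construction, which
  would contradict what the tagging is for;
* an instance lying antisense within a precursor interval still counts as
  in-space. Ambiguity is a statement about where a sequence could
  originate, and an antisense transcript of the same locus is still that
  locus. This is an open modelling question; the choice is recorded here
  and localised in `mirna_space()`/`instance_in_space()`.

Repeat annotation requires full containment of an instance in a repeat
interval, not mere overlap — a k-mer "exists within" a repeat element or it
does not. Exclusive k-mers can legitimately carry repeat classes (a
precursor may itself sit in a repeat), and the synthetic fixture plants
exactly that case.

## Naming

Three schemes are computed for every reported molecule, because each fails
differently:

* **Offset labels** `name|d5|d3` are human-readable but
  database-dependent: `d5`/`d3` are the signed shifts of the isomiR's
  endpoints against a database's mature reference, negative meaning
  upstream. Where databases disagree about the mature endpoints the same
  molecule gets a different label under each; the package reports all of
  them and reconciles nothing.
* **Genome-anchored labels**
  `precursor&WithFlank&chrom|strand|gstart|gend@start.end.length` are
  unambiguous but tied to an assembly.
* **License plates** `prefix-length-payload` are derived from the sequence
  alone and survive both database relabelling and assembly changes. Each
  nucleotide contributes two bits (A=00, C=01, G=10, T=11); the bit string
  is read in 5-bit groups (a trailing short group as its own value) through
  the 32-symbol alphabet `BD0EF1HI2JK3LM4NO5PQ6RS7UV8WX9YZ` — the 22
  letters that are not nucleotide codes, interleaved with the digits. The
  mapping is bijective; the test suite proves the round trip exhaustively
  at length 8 and checks the payload-size formula `ceiling(2L/5)` across
  the 18–26 nt range. For reads with non-templated tails the plate encodes
  the full read sequence (the molecule observed), and the templated core is
  reported separately.

## Variant table construction

Population variants (dbSNP, gnomAD) pass a frequency gate: kept only if
their allele frequency reaches **1%** in at least one reference population
(the input carries the maximum across populations as `max_af`). The gate is
applied to both population sources, since both catalogue germline
variation; somatic mutations (COSMIC) are kept unconditionally. Variants
are applied **one at a time** — co-occurring combinations are not
enumerated, so two variants in one precursor yield two separate families of
variant k-mers. Only k-mers whose span covers the edit are emitted (a
non-covering k-mer is identical to a wild-type k-mer of the same precursor
and would be dropped anyway), and any emitted sequence colliding with a
wild-type key is removed: the two tables' key sets are disjoint by
construction, which is what makes the no-double-counting guarantee
unconditional. A variant whose `ref` allele contradicts the genome aborts
the build with the variant named.

## Read resolution

Resolution order per distinct sequence: wild-type key → variant key → NTA
rescue → unmapped. Each sequence lands in at most one category. The NTA
rescue strips the read's maximal homopolymeric 3′ suffix one base at a
time, re-querying the wild-type table after each strip; the first success
with a core of at least 18 nt wins. Consequences of these choices:

* *Minimal trimming*: the longest templated core is reported, attributing
  the fewest nucleotides to post-transcriptional addition.
* Tails are homopolymeric (runs of one of A/C/G/T), the dominant biological
  case (adenylation/uridylation); mixed tails are out of scope in this
  version.
* Reads longer than 26 nt can only resolve through rescue — the length cap
  applies to the templated portion only.
* Table disjointness makes the wild-type-before-variant order immaterial
  for correctness; it is fixed anyway so the pipeline is order-deterministic
  by specification rather than by accident.

Quantification is sequence-oriented: a sequence's count attaches to its one
output row regardless of how many precursor placements or genomic copies it
has. Both RPM denominators are reported (`rpm_all` over total input reads,
`rpm_mapped` over mapped reads) because downstream tools disagree about
which they want; Σ `rpm_mapped` = 10⁶ exactly whenever anything maps, and a
zero-mapped run reports zeros with a flag rather than NaN.

## Output formats

The TSV output has one row per distinct reported sequence, with placements
and labels as delimited lists within the row, so no abundance is ever
repeated; variant-containing isomiRs go to a separate file and carry
neither exclusivity nor repeat annotation (their sequence is absent from
the genome, so neither attribute is defined). Row order is category, then
plate — deterministic. The mirGFF3 output writes one feature line per
(sequence, precursor) pair, with coordinates on the unexpanded precursor
when the isomiR fits inside it and on the `&WithFlank` sequence otherwise;
the `Variant` attribute uses the mirGFF3 controlled vocabulary, with
`iso_5p:+n` ⇔ `d5 = −n` (nucleotides gained at the 5′ end) and
`iso_3p:+n` ⇔ `d3 = +n`, `iso_add3p:<len>` for tails and `iso_snv` for
variant-containing molecules. The HTML overview is a functional analogue of
a results page — summary, sortable table, and per-precursor panels with
each isomiR rendered in register under its expanded precursor and the
mature span(s) marked — self-contained with no external resources.

## The synthetic reference and what passing tests mean

`make_reference()` generates, deterministically from a seed, a ~100 kb
three-chromosome genome with seven planted precursors covering the
structural cases the method must handle: an overlapping precursor pair (one
sequence, two placements), one locus annotated by both databases with
mature references differing by 2 nt at the 3′ end (the same molecule is
`|0|0` under one and `|0|-2` under the other), decoy copies of one isomiR
planted outside miRNA-space on both strands (forcing a known
exclusive/ambiguous partition), repeat intervals containing the decoys and
one whole precursor, and five variants (a common SNP, a sub-threshold SNP
that must be filtered, a gnomAD insertion and two COSMIC entries including
a deletion). `default_read_recipe()` emulates a small pre-trimmed library
over these loci: reference-identical isomiRs dominate, endpoint variants at
lower counts, ~8% NTA-tailed reads, ~19% variant-allele reads, plus junk,
an `N`-containing and a too-short read. Counts are exact rather than
sampled: the simulator's purpose is ground truth.

Scale choices: the mini-genome is small enough that the quadratic
position-by-position scanning oracle, the nested-loop enumeration oracle
and the all-pairs containment oracles run in seconds, yet large enough
that accidental 18-mer collisions are vanishingly unlikely, so planted
truth is exact truth. The full test suite (≈900 assertions) completes in
under a minute.

What the fixture does *not* emulate: sequencing error, quality-score
structure, adapter read-through, expression dispersion, multi-variant
haplotypes, and genuine genome-scale ambiguity statistics (a 100 kb random
genome has far fewer chance k-mer collisions than a real assembly, where
ambiguity fractions are driven by repeat families and paralogy). Passing
tests therefore certify the *machinery* — exhaustiveness, determinism,
labelling arithmetic, no double counting — not field performance on real
libraries.

## Known limitations

* Closed-world by design: nothing outside the enumerated precursor
  universe is ever reported.
* Mixed-nucleotide 3′ tails are not rescued.
* Variant isomiRs report placements on the variant-modified precursor
  coordinate system; for indels these are shifted by one relative to the
  wild-type precursor downstream of the edit.
* The genome search is held to its scanning oracle on fixtures; the
  `matchPDict`-based implementation is exact, but genome-scale builds are
  an offline, compute-heavy step by nature.
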