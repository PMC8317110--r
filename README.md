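# isomirs

Deterministic, exhaustive identification and quantification of microRNA
isoforms (**isomiRs**) directly from adapter-trimmed short RNA-seq reads —
without a read aligner and without a run-time copy of the genome.

## The problem

A miRNA precursor arm does not produce a single mature sequence but a cloud
of co-existing isoforms that differ by a few nucleotides at their 5′ and/or
3′ termini. Which isoform dominates depends on tissue, disease state and
personal attributes, and is frequently *not* the sequence a public database
lists as the "reference" mature miRNA. Profiling these molecules with a
general-purpose aligner is fragile: permissive alignment settings confound
the true genomic origin of 18–26 nt reads, sequences shared by several loci
get split or dropped arbitrarily, and isoforms that stray past annotated
precursor boundaries are lost.

`isomirs` takes the lookup-table route instead. An **offline build stage**
enumerates, once, every candidate isomiR a reference set of precursors can
template, and annotates each candidate exhaustively against the whole
genome. The **online profile stage** is then a sequence of exact hash
lookups — deterministic, exhaustive, and with no double counting.

## The method

*Build stage* (`build_bundle()`):

1. Each precursor is expanded with 6 nt of genomic flank on each side, so
   isoforms that overrun a (possibly truncated) database annotation are
   still representable. **miRNA-space** is the union of these expanded
   intervals.
2. Every substring of every expanded precursor with length 18–26 nt is a
   candidate isomiR. Every candidate is located exhaustively on both
   strands of every chromosome (exact matches, overlapping occurrences
   included). A candidate whose every genomic instance lies inside
   miRNA-space is **exclusive** (`Y`); one with at least one instance
   outside is **ambiguous** (`N`).
3. Instances fully contained in RepeatMasker intervals attach their repeat
   class (the 20 standard classes) to the candidate.
4. Catalogued variants — common SNPs (dbSNP/gnomAD, kept when their allele
   frequency reaches 1% in at least one reference population) and somatic
   mutations (COSMIC, kept unconditionally); single-nucleotide
   substitutions, insertions and deletions — are applied one at a time to
   the expanded precursors, and every edited k-mer covering the edit goes
   into a second, disjoint **variant table**.

*Profile stage* (`profile_reads()`): reads are collapsed to a frequency
table; each distinct sequence is resolved once — wild-type table first,
then variant table, then a **3′ non-templated addition rescue** that strips
the terminal homopolymer one base at a time and re-queries after each strip
(minimal trimming wins). Counts are per distinct sequence, never split
across placements: Σ category counts + unmapped = total, exactly.

Every reported molecule carries three naming schemes:

- **offset labels** `name|d5|d3` — signed endpoint shifts against each
  database's mature reference (e.g. `hsa-miR-142-5p|-2|-3`), reported for
  *every* database side by side, disagreements preserved;
- **genome-anchored labels**
  `precursor&WithFlank&chrom|strand|gstart|gend@start.end.length`;
- **license plates** `iso-<length>-<payload>` — a sequence-derived,
  assembly-independent bijective identifier
  (`encode_plate("CCCATAAAGTAGAAAGCACT")` → `iso-20-KQB3FBPI`).

Results are written as tab-separated text (variant-containing isomiRs in a
separate file), mirGFF3 (`iso_5p`/`iso_3p`/`iso_add3p`/`iso_snv` controlled
vocabulary) and a self-contained sortable HTML overview.

## Worked example

The package ships a seeded synthetic reference (three chromosomes, ~100 kb,
seven planted precursors including an overlapping pair and a locus
annotated by two databases with different mature endpoints, decoy copies
outside miRNA-space, repeat intervals, five variants) and a read simulator:

```r
library(isomirs)

ref    <- make_reference()
bundle <- build_bundle(ref$precursors, ref$matures, ref$genome,
                       ref$repeats, ref$variants,
                       reference_set = "synthetic", genome_tag = "mini")
bundle
#> <isomir_bundle> synthetic / mini (flank 6, k 18-26)
#>   wild-type k-mers: 2475 (3213 placements, 2511 genomic instances)
#>   variant k-mers:   765

recipe <- default_read_recipe(ref, bundle)
simulate_reads(recipe, "reads.fastq.gz", seed = 7)
profile <- profile_reads("reads.fastq.gz", bundle)
profile
#> <isomir_profile> 312 reads, 297 mapped (95.2%)
#>   exclusive 197 | ambiguous 40 | variant 60 | NTA-rescued 24 | unmapped 15
#>   distinct isomiRs reported: 14
```

The 40 ambiguous reads are the planted isomiR whose sequence was copied to
two decoy loci outside miRNA-space; its row is tagged `N` with repeat class
`LINE` (both decoys sit inside planted LINE intervals). The 24 NTA-rescued
reads carry homopolymer tails (`nta:A2`, `nta:A3` in the `type` column) and
inherit the exclusivity of their templated core. The 60 variant reads
resolve in the variant table and report their `dbSNP:`/`gnomAD:`/`COSMIC:`
identifiers; the sub-1%-frequency SNP planted in the fixture is absent from
the tables by design. `tidy(profile)` returns the per-isomiR tibble,
`glance(profile)` the run summary, and

```r
write_profile_tsv(profile, bundle, "out")
write_profile_gff3(profile, bundle, "out.gff3")
write_profile_html(profile, bundle, "out.html")
```

emit the three output formats. A command-line front end wrapping the same
functions is installed at `system.file("cli", "isomir", package = "isomirs")`
with `build`, `profile` and `plates` subcommands.

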