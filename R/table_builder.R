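# Offline table construction. Candidate isomiRs are every 18-26 nt substring
# of the flank-expanded precursors; each candidate is then sought exhaustively
# in the whole genome (both strands, overlapping occurrences included) so the
# online phase never needs an aligner or a genome copy. The search runs
# through Biostrings::matchPDict grouped by k-mer width; tests hold it to a
# quadratic position-by-position scanning oracle.

REPEAT_CLASSES <- c(
  "SINE", "SINE?", "LINE", "RC", "RC?", "RNA", "scRNA", "srpRNA", "rRNA",
  "tRNA", "DNA", "DNA?", "snRNA", "Retroposon", "Unknown", "LTR", "LTR?",
  "Satellite", "Low_complexity", "Simple_repeat")

#' Enumerate candidate isomiRs from expanded precursors
#'
#' Every substring with length in `[kmin, kmax]` of every expanded precursor
#' is a candidate isomiR; each candidate is recorded with all of its
#' placements (precursor, start position). Substrings containing `N` are
#' excluded: exact-match lookup is undefined for them.
#'
#' @param expanded Tibble from [expand_precursors()].
#' @param kmin,kmax Candidate length bounds in nucleotides (defaults 18, 26).
#' @return A tibble with columns `seq`, `precursor`, `start`, `length`; one
#'   row per placement, so a sequence occurring at several positions or in
#'   several precursors has several rows.
#' @export
enumerate_candidates <- function(expanded, kmin = 18L, kmax = 26L) {
  stopifnot(kmin >= 1L, kmax >= kmin)
  out <- purrr::map2(expanded$name, expanded$seq, function(nm, s) {
    substrings_in_range(s, kmin, kmax) |>
      mutate(precursor = nm)
  }) |>
    bind_rows()
  if (nrow(out) == 0L) {
    return(tibble(seq = character(), precursor = character(),
                  start = integer(), length = integer()))
  }
  out |>
    filter(!str_detect(.data$kmer, "N")) |>
    select(seq = "kmer", "precursor", "start", "length") |>
    arrange(.data$seq, .data$precursor, .data$start)
}

#' Find every genomic instance of a set of sequences
#'
#' Exhaustive exact search of each query on both strands of every
#' chromosome, including overlapping occurrences. Coordinates are 1-based
#' inclusive on the forward genomic axis; a `-` strand instance means the
#' query equals the reverse complement of the genomic slice.
#'
#' @param seqs Character vector of DNA queries (deduplicated internally).
#' @param genome A [Biostrings::DNAStringSet].
#' @return A tibble with columns `seq`, `chrom`, `strand`, `start`, `end`,
#'   ordered by (seq, chrom, start, strand).
#' @export
find_genomic_instances <- function(seqs, genome) {
  seqs <- unique(seqs)
  empty <- tibble(seq = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer())
  if (length(seqs) == 0L) return(empty)
  assert_dna(seqs, "query")
  hits_one_strand <- function(qs, strand) {
    # on "-" we search the reverse complement of each query forward
    pats <- if (strand == "-") revcomp(qs) else qs
    by_w <- split(seq_along(qs), nchar(pats))
    purrr::map(by_w, function(idx) {
      pd <- Biostrings::PDict(pats[idx])
      purrr::imap(as.list(genome), function(chrom_seq, chrom_name) {
        m <- Biostrings::matchPDict(pd, chrom_seq)
        counts <- lengths(m)
        if (sum(counts) == 0L) return(NULL)
        starts <- unlist(lapply(m, Biostrings::start), use.names = FALSE)
        ends <- unlist(lapply(m, Biostrings::end), use.names = FALSE)
        tibble(seq = rep(qs[idx], counts), chrom = chrom_name,
               strand = strand, start = starts, end = ends)
      }) |>
        bind_rows()
    }) |>
      bind_rows()
  }
  bind_rows(empty, hits_one_strand(seqs, "+"), hits_one_strand(seqs, "-")) |>
    arrange(.data$seq, .data$chrom, .data$start, .data$strand)
}

#' The miRNA-space intervals of a reference set
#'
#' miRNA-space is the union of all flank-expanded precursor intervals; it is
#' the region against which exclusivity is judged. Strand is deliberately
#' ignored: ambiguity concerns where a sequence can originate, not its
#' orientation.
#'
#' @param expanded Tibble from [expand_precursors()].
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
mirna_space <- function(expanded) {
  expanded |>
    select("chrom", start = "gstart", end = "gend") |>
    distinct()
}

#' Classify genomic instances as exclusive or ambiguous
#'
#' A sequence is exclusive (`"Y"`) when every one of its genomic instances
#' lies fully inside some miRNA-space interval, and ambiguous (`"N"`) when
#' at least one instance falls outside. There is no third state.
#'
#' @param instances Tibble from [find_genomic_instances()] (columns `seq`,
#'   `chrom`, `start`, `end`); must be complete for each sequence.
#' @param space Tibble from [mirna_space()].
#' @return A tibble with columns `seq`, `exclusive` (`"Y"`/`"N"`).
#' @export
classify_exclusivity <- function(instances, space) {
  if (nrow(instances) == 0L) {
    stop("empty instance list: a table k-mer must occur at least at its ",
         "source locus", call. = FALSE)
  }
  instances$in_space <- instance_in_space(instances, space)
  instances |>
    group_by(.data$seq) |>
    summarise(exclusive = ifelse(all(.data$in_space), "Y", "N"),
              .groups = "drop")
}

# logical vector: is each instance fully contained in a space interval
# on its chromosome?
instance_in_space <- function(instances, space) {
  out <- rep(FALSE, nrow(instances))
  for (ch in unique(instances$chrom)) {
    idx <- which(instances$chrom == ch)
    sp <- space[space$chrom == ch, , drop = FALSE]
    if (nrow(sp) == 0L) next
    q <- IRanges::IRanges(instances$start[idx], instances$end[idx])
    s <- IRanges::IRanges(sp$start, sp$end)
    out[idx] <- IRanges::overlapsAny(q, s, type = "within")
  }
  out
}

#' Validate and load a repeat-element interval table
#'
#' Tab-separated with columns `chrom`, `start`, `end`, `class` (RepeatMasker
#' coordinates, 1-based inclusive). The class must be one of the 20
#' RepeatMasker class names; anything else is rejected at load time.
#'
#' @param path Path to the table.
#' @return A validated tibble.
#' @export
read_repeats <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         class = readr::col_character()))
  validate_repeats(x)
}

validate_repeats <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(c("chrom", "start", "end", "class"), names(x))
  if (length(missing) > 0) {
    stop("repeat table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(x$class), REPEAT_CLASSES)
  if (length(bad) > 0) {
    stop("unknown repeat class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Annotate sequences with containing repeat classes
#'
#' A repeat class is attached to a sequence when at least one of its genomic
#' instances is fully contained in a repeat interval of that class
#' (containment, not mere overlap). Classes are reported sorted and
#' de-duplicated; the empty string means no containing repeat, which is
#' legitimate for exclusive and ambiguous sequences alike.
#'
#' @param instances Tibble from [find_genomic_instances()].
#' @param repeats Repeat interval tibble (see [read_repeats()]).
#' @return A tibble with columns `seq`, `repeat_classes` (comma-joined).
#' @export
annotate_repeats <- function(instances, repeats) {
  repeats <- validate_repeats(repeats)
  if (nrow(instances) == 0L) {
    return(tibble(seq = character(), repeat_classes = character()))
  }
  hits <- purrr::map(unique(instances$chrom), function(ch) {
    idx <- which(instances$chrom == ch)
    rp <- repeats[repeats$chrom == ch, , drop = FALSE]
    if (nrow(rp) == 0L) return(NULL)
    q <- IRanges::IRanges(instances$start[idx], instances$end[idx])
    s <- IRanges::IRanges(rp$start, rp$end)
    ov <- IRanges::findOverlaps(q, s, type = "within")
    tibble(seq = instances$seq[idx][S4Vectors::queryHits(ov)],
           class = rp$class[S4Vectors::subjectHits(ov)])
  }) |>
    bind_rows()
  base <- tibble(seq = unique(instances$seq))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(base |> mutate(repeat_classes = ""))
  }
  agg <- hits |>
    distinct() |>
    group_by(.data$seq) |>
    summarise(repeat_classes = paste(sort(.data$class), collapse = ","),
              .groups = "drop")
  base |>
    left_join(agg, by = "seq") |>
    mutate(repeat_classes = ifelse(is.na(.data$repeat_classes), "",
                                   .data$repeat_classes))
}

#' Read a variant list
#'
#' Tab-separated with columns `id`, `source` (`dbSNP`, `gnomAD` or
#' `COSMIC`), `chrom`, `pos` (1-based), `ref`, `alt` (forward-strand
#' alleles, VCF-style: a shared anchor base for indels is allowed as long as
#' the net edit is a single-nucleotide substitution, insertion or deletion)
#' and `max_af` (the variant's largest allele frequency across the reference
#' populations; ignored for COSMIC).
#'
#' @param path Path to the table.
#' @return A validated tibble.
#' @export
read_variants <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         max_af = readr::col_double(),
                         .default = readr::col_character()))
  validate_variants(x)
}

validate_variants <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(c("id", "source", "chrom", "pos", "ref", "alt", "max_af"),
                     names(x))
  if (length(missing) > 0) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$source %in% c("dbSNP", "gnomAD", "COSMIC"))) {
    stop("variant source must be dbSNP, gnomAD or COSMIC", call. = FALSE)
  }
  sz <- abs(nchar(x$ref) - nchar(x$alt))
  if (any(sz > 1L) || any(pmin(nchar(x$ref), nchar(x$alt)) != 1L) ||
      any(nchar(x$ref) == 1L & nchar(x$alt) == 1L & x$ref == x$alt)) {
    stop("only single-nucleotide substitutions, insertions and deletions ",
         "are supported", call. = FALSE)
  }
  x
}

#' Build the variant k-mer table
#'
#' Population variants (dbSNP, gnomAD) are kept only when their minor allele
#' frequency reaches 1% in at least one reference population; somatic
#' mutations (COSMIC) are kept unconditionally. Each kept variant falling
#' inside an expanded precursor is applied on its own to the precursor
#' sequence; every k-mer of the edited sequence whose span covers the edit
#' (length within `[kmin, kmax]` after editing) is emitted, minus any
#' sequence already present in the wild-type table — the two tables' key
#' sets stay disjoint so a read can never be counted twice. Identical
#' sequences generated by several (variant, precursor) pairs are merged and
#' all generators listed.
#'
#' @param expanded Tibble from [expand_precursors()].
#' @param variants Variant tibble (see [read_variants()]).
#' @param genome A [Biostrings::DNAStringSet], used to check each variant's
#'   `ref` allele against the reference sequence.
#' @param wildtype_seqs Character vector of wild-type table keys.
#' @param kmin,kmax Length bounds for the emitted k-mers.
#' @param maf_min Population-frequency threshold (default 0.01).
#' @return A list with `table` (tibble: `seq`, `templated_seq`,
#'   `variant_ids`) and `placements` (tibble: `seq`, `precursor`, `start`,
#'   `length`, coordinates on the variant-modified expanded precursor).
#' @export
build_variant_table <- function(expanded, variants, genome, wildtype_seqs,
                                kmin = 18L, kmax = 26L, maf_min = 0.01) {
  variants <- validate_variants(variants)
  kept <- variants |>
    filter(.data$source == "COSMIC" |
             (!is.na(.data$max_af) & .data$max_af >= maf_min))
  empty <- list(
    table = tibble(seq = character(), templated_seq = character(),
                   variant_ids = character()),
    placements = tibble(seq = character(), precursor = character(),
                        start = integer(), length = integer()))
  if (nrow(kept) == 0L || nrow(expanded) == 0L) return(empty)

  rows <- list()
  for (vi in seq_len(nrow(kept))) {
    v <- kept[vi, ]
    # reduce a VCF-style (ref, alt) pair to a normalised single-base edit
    edit <- normalise_edit(v$ref, v$alt, v$pos)
    ref_slice <- as.character(Biostrings::subseq(
      genome[[v$chrom]], start = v$pos, width = nchar(v$ref)))
    if (ref_slice != v$ref) {
      stop(sprintf("variant %s: ref allele %s does not match genome (%s)",
                   v$id, v$ref, ref_slice), call. = FALSE)
    }
    host <- expanded |>
      filter(.data$chrom == v$chrom,
             .data$gstart <= edit$gpos, edit$gpos <= .data$gend)
    for (pi in seq_len(nrow(host))) {
      e <- host[pi, ]
      rows[[length(rows) + 1L]] <-
        variant_kmers_one(e, edit, v, kmin, kmax)
    }
  }
  emitted <- bind_rows(rows)
  if (nrow(emitted) == 0L) return(empty)
  emitted <- emitted |> filter(!(.data$seq %in% wildtype_seqs))
  if (nrow(emitted) == 0L) return(empty)
  tab <- emitted |>
    distinct(.data$seq, .data$templated_seq, .data$variant_id) |>
    group_by(.data$seq) |>
    summarise(
      templated_seq = paste(sort(unique(.data$templated_seq)), collapse = ","),
      variant_ids = paste(sort(unique(.data$variant_id)), collapse = ","),
      .groups = "drop")
  plc <- emitted |>
    distinct(.data$seq, .data$precursor, .data$start, .data$length) |>
    arrange(.data$seq, .data$precursor, .data$start)
  list(table = tab, placements = plc)
}

# Turn a VCF-style (ref, alt) at pos into one of:
#   sub: replace one base at gpos; ins: insert one base after gpos;
#   del: delete one base at gpos. Shared leading anchor bases are consumed.
normalise_edit <- function(ref, alt, pos) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(type = "sub", gpos = pos, base = alt))
  }
  if (nchar(alt) > nchar(ref)) {   # insertion, e.g. ref=G alt=GA
    if (substr(alt, 1L, 1L) != ref) {
      stop("insertion alleles must share their anchor base", call. = FALSE)
    }
    return(list(type = "ins", gpos = pos, base = substr(alt, 2L, 2L)))
  }
  if (substr(ref, 1L, 1L) != alt) {  # deletion, e.g. ref=GA alt=G
    stop("deletion alleles must share their anchor base", call. = FALSE)
  }
  list(type = "del", gpos = pos + 1L)
}

# Apply one edit to one expanded precursor; emit covering k-mers.
variant_kmers_one <- function(e, edit, v, kmin, kmax) {
  s <- e$seq
  p <- genomic_to_expanded(e, edit$gpos)
  if (e$strand == "+") {
    base <- edit$base
    ins_at <- p            # insert after precursor position p
  } else {
    base <- if (edit$type != "del") complement_base(edit$base) else NA_character_
    ins_at <- p - 1L       # "after gpos" on the genome = before p in precursor
  }
  if (edit$type == "sub") {
    edited <- paste0(substr(s, 1L, p - 1L), base,
                     substr(s, p + 1L, nchar(s)))
    lo <- p
    hi <- p
  } else if (edit$type == "ins") {
    edited <- paste0(substr(s, 1L, ins_at), base,
                     substr(s, ins_at + 1L, nchar(s)))
    lo <- ins_at + 1L
    hi <- ins_at + 1L
  } else {
    edited <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
    # a deletion leaves a junction between edited positions p-1 and p;
    # a k-mer covers it when it includes both sides
    lo <- p - 1L
    hi <- p
  }
  sub <- substrings_in_range(edited, kmin, kmax)
  if (nrow(sub) == 0L) return(NULL)
  cov <- if (edit$type == "del") {
    sub$start <= lo & (sub$start + sub$length - 1L) >= hi
  } else {
    sub$start <= hi & (sub$start + sub$length - 1L) >= lo
  }
  sub <- sub[cov & !grepl("N", sub$kmer), , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  # templated counterpart: the wild-type bases occupying the same span of
  # the unedited precursor (span endpoints mapped back through the edit)
  shift <- switch(edit$type, sub = 0L, ins = -1L, del = 1L)
  t_start <- ifelse(sub$start <= lo, sub$start, sub$start + shift)
  t_end_edit <- sub$start + sub$length - 1L
  t_end <- ifelse(t_end_edit < lo, t_end_edit, t_end_edit + shift)
  t_start <- pmax(1L, t_start)
  t_end <- pmin(nchar(s), t_end)
  tibble(seq = sub$kmer,
         templated_seq = substring(s, t_start, t_end),
         variant_id = paste0(v$source, ":", v$id),
         precursor = e$name,
         start = sub$start,
         length = sub$length)
}
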