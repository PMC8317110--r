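# Synthetic reference and read simulator. The mini-genome stands in for a
# real assembly plus miRNA/repeat/variant annotations: it is generated from
# a seed, every planted feature is recorded in truth tables, and the files
# written are in exactly the formats the real pipeline consumes. The layout
# deliberately mirrors the situations the profiler must handle: a pair of
# overlapping precursors, one locus annotated by two databases with
# different mature endpoints, decoy copies of an isomiR outside miRNA-space
# (forcing ambiguity), repeat elements containing those decoys, and a mix
# of common, rare and somatic variants.

#' Specification of the synthetic reference
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @return A list of generation parameters: chromosome sizes (three
#'   chromosomes, ~100 kb total — large enough to host decoys and repeats,
#'   small enough that a quadratic scanning oracle over it is fast),
#'   precursor length, flank and the k range.
#' @export
fixture_spec <- function(seed = 20210120L) {
  list(seed = as.integer(seed),
       chrom_sizes = c(chrA = 40000L, chrB = 35000L, chrC = 25000L),
       precursor_length = 60L,
       decoy_chroms = c("chrC", "chrB"),
       decoy_strands = c("+", "-"),
       decoy_starts = c(18001L, 30001L),
       flank = 6L, kmin = 18L, kmax = 26L)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build the synthetic reference
#'
#' Generates the mini-genome and all annotation tables, plants the decoy
#' copies and repeat intervals, and records every planted feature in truth
#' tables. Construction is fully deterministic in `spec$seed`. A decoy that
#' would land inside miRNA-space is a specification error and raises.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `isomir_fixture`: `genome`
#'   ([Biostrings::DNAStringSet]), `precursors`, `matures`, `repeats`,
#'   `variants` (annotation tibbles), `truth` (list of truth tibbles:
#'   `decoys`, `variant_kept`) and `spec`.
#' @export
make_reference <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    chroms <- vapply(spec$chrom_sizes, random_dna, character(1))
    L <- spec$precursor_length

    precursors <- tibble(
      name = c("syn-mir-1", "syn-mir-2", "syn-mir-3", "syn-mir-4",
               "syn-mir-5c", "syn-mir-5b", "syn-mir-6"),
      db = c("mircarta", "mircarta", "mircarta", "mircarta",
             "mircarta", "mirbase", "mircarta"),
      chrom = c("chrA", "chrA", "chrA", "chrA", "chrB", "chrB", "chrC"),
      strand = c("+", "-", "+", "+", "+", "+", "-"),
      start = c(5001L, 12001L, 20001L, 20021L, 8001L, 8001L, 6001L),
      end = NA_integer_)
    precursors$end <- precursors$start + L - 1L
    # syn-mir-3 / syn-mir-4 overlap by 40 nt; syn-mir-5c and syn-mir-5b are
    # the same locus annotated by the two databases.

    matures <- tibble(
      precursor = c("syn-mir-1", "syn-mir-2", "syn-mir-3", "syn-mir-4",
                    "syn-mir-5c", "syn-mir-5b", "syn-mir-6"),
      name = c("syn-miR-1-5p", "syn-miR-2-5p", "syn-miR-3-5p",
               "syn-miR-4-5p", "syn-miR-5-5p", "syn-miR-5-5p",
               "syn-miR-6-5p"),
      offset = c(10L, 10L, 12L, 10L, 11L, 11L, 10L),
      length = c(22L, 22L, 22L, 22L, 20L, 22L, 22L))
    # the database disparity: at the syn-mir-5 locus, the mirbase mature is
    # 2 nt longer at its 3' end than the mircarta mature.

    # decoy copies: the mircarta 0|0 isomiR of syn-mir-2, planted verbatim
    # on chrC and reverse-complemented on chrB, both far from any precursor
    m2 <- matures[matures$precursor == "syn-mir-2", ]
    p2 <- precursors[precursors$name == "syn-mir-2", ]
    p2_seq <- revcomp(substr(chroms[["chrA"]], p2$start, p2$end))
    decoy_seq <- substr(p2_seq, m2$offset, m2$offset + m2$length - 1L)
    decoys <- tibble(
      seq = decoy_seq,
      chrom = spec$decoy_chroms,
      strand = spec$decoy_strands,
      start = spec$decoy_starts)
    decoys$end <- decoys$start + nchar(decoys$seq) - 1L
    for (i in seq_len(nrow(decoys))) {
      planted <- if (decoys$strand[i] == "+") decoys$seq[i] else revcomp(decoys$seq[i])
      ch <- decoys$chrom[i]
      chroms[[ch]] <- paste0(substr(chroms[[ch]], 1L, decoys$start[i] - 1L),
                             planted,
                             substr(chroms[[ch]], decoys$end[i] + 1L,
                                    nchar(chroms[[ch]])))
    }

    genome <- Biostrings::DNAStringSet(chroms)
    expanded <- expand_precursors(precursors, genome, flank = spec$flank)
    space <- mirna_space(expanded)
    decoy_in_space <- instance_in_space(decoys, space)
    if (any(decoy_in_space)) {
      stop("fixture specification error: decoy planted inside miRNA-space",
           call. = FALSE)
    }

    repeats <- tibble(
      chrom = c("chrC", "chrB", "chrA", "chrC", "chrC"),
      start = c(17951L, 29951L, 30001L, 6001L - 20L, 2001L),
      end = c(18100L, 30100L, 30200L, 6060L + 20L, 2200L),
      class = c("LINE", "LINE", "SINE", "Simple_repeat", "Satellite"))
    # both decoy copies sit inside LINE intervals; the Simple_repeat
    # interval contains the whole expanded syn-mir-6, so exclusive k-mers
    # can legitimately carry a repeat class; SINE and Satellite contain
    # nothing of interest.
    repeats <- validate_repeats(repeats)

    base_at <- function(ch, pos) substr(chroms[[ch]], pos, pos)
    other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
    v_pos <- c(5031L, 12030L, 8026L, 6025L, 12040L)
    v_chrom <- c("chrA", "chrA", "chrB", "chrC", "chrA")
    v_ref <- vapply(seq_along(v_pos),
                    function(i) base_at(v_chrom[i], v_pos[i]), character(1))
    variants <- tibble(
      id = c("rs9000001", "rs9000002", "COSN7700001", "gn0000003",
             "COSN7700002"),
      source = c("dbSNP", "dbSNP", "COSMIC", "gnomAD", "COSMIC"),
      chrom = v_chrom,
      pos = v_pos,
      ref = c(v_ref[1], v_ref[2], v_ref[3],
              v_ref[4], paste0(v_ref[5], base_at("chrA", 12041L))),
      alt = c(other_base(v_ref[1]), other_base(v_ref[2]),
              other_base(v_ref[3]), paste0(v_ref[4], "A"), v_ref[5]),
      max_af = c(0.15, 0.002, NA, 0.05, NA))
    # rs9000002 sits below the 1% frequency gate and must be filtered out
    # at table-build time; the two COSMIC entries (a substitution and a
    # 1-nt deletion) are somatic and kept unconditionally.
    variants <- validate_variants(variants)

    structure(list(genome = genome, precursors = precursors,
                   matures = matures, repeats = repeats, variants = variants,
                   truth = list(decoys = decoys,
                                variant_kept = variants$id[
                                  variants$source == "COSMIC" |
                                    (!is.na(variants$max_af) &
                                       variants$max_af >= 0.01)]),
                   spec = spec),
              class = "isomir_fixture")
  })
}

#' Write the synthetic reference to disk
#'
#' Emits the same file formats the real pipeline consumes: a genome FASTA
#' and tab-separated precursor, mature, repeat and variant tables, plus the
#' truth tables.
#'
#' @param ref An `isomir_fixture` from [make_reference()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "isomir_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  readr::write_tsv(ref$precursors, file.path(dir, "precursors.tsv"))
  readr::write_tsv(ref$matures, file.path(dir, "matures.tsv"))
  readr::write_tsv(ref$repeats, file.path(dir, "repeats.tsv"))
  readr::write_tsv(ref$variants, file.path(dir, "variants.tsv"))
  readr::write_tsv(ref$truth$decoys, file.path(dir, "truth_decoys.tsv"))
  invisible(dir)
}

#' Default read recipe for the synthetic reference
#'
#' Emulates a small, pre-trimmed short RNA-seq library over the planted
#' loci: reference-identical isomiRs dominate, 5'/3' endpoint variants are
#' present at lower counts, ~10% of reads carry a 3' non-templated
#' homopolymer tail, a few percent carry a planted variant allele, and a
#' small remainder is unmappable junk plus an N-containing and a too-short
#' read. Counts are exact (no sampling noise): the simulator's job is
#' ground truth, not realism of the count distribution.
#'
#' @param ref An `isomir_fixture`.
#' @param bundle The `isomir_bundle` built from `ref` (used to verify that
#'   planted NTA reads are genuinely absent from the wild-type table and
#'   that junk reads are unmappable).
#' @return A tibble with columns `seq`, `kind` (`wildtype`, `nta`,
#'   `variant`, `junk`, `filtered`), `core`, `tail`, `count`.
#' @export
default_read_recipe <- function(ref, bundle) {
  spec <- ref$spec
  expanded <- bundle$expanded
  iso_seq <- function(precursor, d5 = 0L, d3 = 0L) {
    e <- expanded[expanded$name == precursor, ]
    m <- ref$matures[ref$matures$precursor == precursor, ]
    s <- m$offset + e$pad5 + d5
    en <- m$offset + e$pad5 + m$length - 1L + d3
    substr(e$seq, s, en)
  }
  wt <- tibble(
    seq = c(iso_seq("syn-mir-1"), iso_seq("syn-mir-1", d5 = -1L),
            iso_seq("syn-mir-1", d3 = 2L), iso_seq("syn-mir-2"),
            iso_seq("syn-mir-3"), iso_seq("syn-mir-5c"),
            iso_seq("syn-mir-6"), iso_seq("syn-mir-6", d5 = 1L, d3 = -1L)),
    kind = "wildtype",
    count = c(60L, 12L, 18L, 40L, 25L, 30L, 20L, 8L))
  wt <- wt |> distinct(.data$seq, .keep_all = TRUE)

  # NTA reads: core + homopolymer tail whose base differs from the next
  # templated base, so the untrimmed read cannot be a wild-type key
  nta_core <- c(iso_seq("syn-mir-1"), iso_seq("syn-mir-6"))
  nta_host <- c("syn-mir-1", "syn-mir-6")
  tails <- vapply(seq_along(nta_core), function(i) {
    e <- expanded[expanded$name == nta_host[i], ]
    pos_after <- regexpr(nta_core[i], e$seq, fixed = TRUE)[1] +
      nchar(nta_core[i])
    nxt <- substr(e$seq, pos_after, pos_after)
    base <- setdiff(c("A", "T", "C", "G"), nxt)[1]
    strrep(base, i + 1L)   # tails of length 2 and 3
  }, character(1))
  nta <- tibble(seq = paste0(nta_core, tails), kind = "nta",
                core = nta_core, tail = tails, count = c(15L, 9L))
  bad <- nta$seq %in% bundle$wildtype$seq | nta$seq %in% bundle$variant$seq
  if (any(bad)) {
    stop("fixture error: planted NTA read collides with a table key",
         call. = FALSE)
  }

  # variant reads: one representative k-mer per kept variant table entry
  if (nrow(bundle$variant) > 0L) {
    vr <- bundle$variant |>
      group_by(.data$variant_ids) |>
      dplyr::slice_head(n = 1L) |>
      ungroup() |>
      select("seq") |>
      mutate(kind = "variant",
             count = 10L + 2L * row_number())
  } else {
    vr <- tibble(seq = character(), kind = character(), count = integer())
  }

  junk <- with_seed(spec$seed + 1L, {
    out <- character(0)
    g <- as.character(ref$genome)
    while (length(out) < 2L) {
      cand <- random_dna(22L)
      hit <- any(vapply(g, function(ch) {
        grepl(cand, ch, fixed = TRUE) || grepl(revcomp(cand), ch, fixed = TRUE)
      }, logical(1)))
      if (!hit && !(cand %in% bundle$variant$seq)) out <- c(out, cand)
    }
    out
  })
  junk <- tibble(seq = junk, kind = "junk", count = c(6L, 4L))
  filtered <- tibble(
    seq = c(paste0("ACGTN", substr(wt$seq[1], 6L, nchar(wt$seq[1]))),
            substr(wt$seq[1], 1L, 16L)),
    kind = "filtered", count = c(2L, 3L))
  bind_rows(wt, nta, vr, junk, filtered) |>
    mutate(core = ifelse(is.na(.data$core), .data$seq, .data$core),
           tail = ifelse(is.na(.data$tail), "", .data$tail))
}

#' Simulate a FASTQ read set from a recipe
#'
#' Emits each recipe sequence exactly `count` times with placeholder
#' quality strings, in an order shuffled deterministically by `seed`.
#'
#' @param recipe Tibble with columns `seq` and `count` (e.g. from
#'   [default_read_recipe()]); requesting a non-positive count is an error.
#' @param path Output FASTQ path; a `.gz` suffix gzips the file.
#' @param seed Seed for the read-order shuffle.
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(recipe, path, seed = 1L) {
  stopifnot(all(c("seq", "count") %in% names(recipe)))
  if (nrow(recipe) > 0L && any(recipe$count < 1L)) {
    stop("recipe counts must be positive", call. = FALSE)
  }
  seqs <- rep(recipe$seq, recipe$count)
  seqs <- with_seed(seed, sample(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs) > 0L) {
    recs <- paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
                   strrep("I", nchar(seqs)))
    writeLines(recs, con)
  } else {
    # a zero-read recipe still yields a valid (empty) FASTQ
    writeLines(character(0), con)
  }
  invisible(path)
}
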