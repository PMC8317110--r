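# Online phase. Reads are collapsed to a frequency table, each distinct
# sequence is resolved against the lookup tables exactly once, and counts
# are carried per sequence (never split across placements), so no read is
# ever double-counted no matter how many genomic copies its isomiR has.

#' Collapse a FASTQ file to a read frequency table
#'
#' Reads must already be quality-trimmed and adapter-free; the file may be
#' plain or gzipped FASTQ. Identical sequences are collapsed to one row with
#' a count. Reads containing `N` or shorter than `kmin` stay in the totals
#' but are flagged ineligible for lookup.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @param kmin Minimum eligible read length (default 18).
#' @return A tibble with columns `seq`, `count`, `eligible`, carrying
#'   attributes `total_reads`, `reads_with_n`, `reads_too_short`.
#' @export
load_reads <- function(path, kmin = 18L) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  seqs <- as.character(reads)
  read_frequency_table(seqs, kmin = kmin)
}

#' @rdname load_reads
#' @param seqs Character vector of read sequences (one element per read).
#' @export
read_frequency_table <- function(seqs, kmin = 18L) {
  total <- length(seqs)
  if (total == 0L) {
    out <- tibble(seq = character(), count = integer(), eligible = logical())
  } else {
    counts <- table(seqs)
    out <- tibble(seq = names(counts), count = as.integer(counts)) |>
      mutate(eligible = !str_detect(.data$seq, "[^ACGT]") &
               str_length(.data$seq) >= kmin) |>
      arrange(.data$seq)
  }
  has_n <- str_detect(out$seq, "[^ACGT]")
  attr(out, "total_reads") <- total
  attr(out, "reads_with_n") <- sum(out$count[has_n])
  attr(out, "reads_too_short") <-
    sum(out$count[!has_n & str_length(out$seq) < kmin])
  class(out) <- c("read_freq", class(out))
  out
}

#' Resolve one distinct read sequence against the lookup tables
#'
#' Resolution order is fixed for determinism: (1) an exact wild-type table
#' key is a `wildtype` hit; (2) an exact variant table key is a `variant`
#' hit; (3) otherwise the 3' non-templated-addition rescue strips the
#' maximal homopolymeric 3' suffix one nucleotide at a time, re-querying the
#' wild-type table after each strip — the first success whose templated core
#' is at least `kmin` long is an `nta` hit (minimal trimming wins, so the
#' fewest possible nucleotides are attributed to post-transcriptional
#' addition); (4) otherwise the read is unmapped. Each read lands in at most
#' one category.
#'
#' @param seq One read sequence.
#' @param bundle An `isomir_bundle` (see [build_bundle()] / [load_bundle()]).
#' @return A one-row tibble (`seq`, `category`, `templated_core`, `tail`) or
#'   `NULL` when unmapped.
#' @export
resolve_read <- function(seq, bundle) {
  res <- resolve_sequences(seq, bundle)
  if (nrow(res) == 0L) NULL else res
}

# Vectorised resolution of many distinct sequences; unmapped ones dropped.
resolve_sequences <- function(seqs, bundle) {
  kmin <- bundle$metadata$kmin
  wt <- seqs %in% bundle$wildtype$seq
  vr <- !wt & seqs %in% bundle$variant$seq
  rest <- seqs[!wt & !vr]
  rescued <- purrr::map(rest, function(s) nta_rescue(s, bundle, kmin)) |>
    bind_rows()
  out <- bind_rows(
    tibble(seq = seqs[wt], category = "wildtype",
           templated_core = seqs[wt], tail = ""),
    tibble(seq = seqs[vr], category = "variant",
           templated_core = seqs[vr], tail = ""),
    rescued)
  out |> arrange(.data$seq)
}

# Strip the homopolymeric 3' suffix one base at a time, re-querying the
# wild-type table after each strip.
nta_rescue <- function(s, bundle, kmin) {
  n <- nchar(s)
  last <- substr(s, n, n)
  run <- n - nchar(sub(paste0(last, "+$"), "", s))
  max_strip <- min(run, n - kmin)
  if (max_strip < 1L) return(NULL)
  for (k in seq_len(max_strip)) {
    core <- substr(s, 1L, n - k)
    if (core %in% bundle$wildtype$seq) {
      return(tibble(seq = s, category = "nta", templated_core = core,
                    tail = strrep(last, k)))
    }
  }
  NULL
}

#' Profile a read set against a lookup-table bundle
#'
#' The complete online phase: resolve every distinct eligible sequence,
#' attach annotations (placements, exclusivity, repeat classes, variant
#' identifiers — NTA hits inherit the annotation of their templated core),
#' quantify in raw counts and reads-per-million, and compute the run
#' summary. Both RPM denominators are reported: all input reads and mapped
#' reads only.
#'
#' @param reads A read frequency table ([load_reads()]) or a path to a
#'   FASTQ file.
#' @param bundle An `isomir_bundle`.
#' @return An object of class `isomir_profile`: a list with `hits` (one row
#'   per reported distinct sequence), `summary` (one-row tibble) and
#'   `metadata`.
#' @export
profile_reads <- function(reads, bundle) {
  stopifnot(inherits(bundle, "isomir_bundle"))
  if (is.character(reads)) reads <- load_reads(reads, kmin = bundle$metadata$kmin)
  stopifnot(inherits(reads, "read_freq"))
  total <- attr(reads, "total_reads")
  eligible <- reads |> filter(.data$eligible)
  res <- resolve_sequences(eligible$seq, bundle)
  hits <- res |>
    left_join(eligible |> select("seq", "count"), by = "seq") |>
    left_join(bundle$wildtype |>
                rename(core_seq = "seq"),
              by = c(templated_core = "core_seq")) |>
    left_join(bundle$variant |>
                select("seq", "variant_ids", var_templated = "templated_seq"),
              by = "seq") |>
    mutate(
      exclusive = ifelse(.data$category == "variant", NA_character_,
                         .data$exclusive),
      repeat_classes = ifelse(.data$category == "variant", NA_character_,
                              .data$repeat_classes),
      templated_core = ifelse(.data$category == "variant",
                              .data$var_templated, .data$templated_core),
      variant_ids = ifelse(.data$category == "variant", .data$variant_ids,
                           NA_character_),
      plate = encode_plate(.data$seq)
    ) |>
    select(-"var_templated")
  mapped <- sum(hits$count)
  hits <- hits |>
    mutate(rpm_all = .data$count * 1e6 / total,
           rpm_mapped = if (mapped > 0) .data$count * 1e6 / mapped else 0) |>
    arrange(.data$category, .data$plate)
  smry <- profile_summary(hits, total, mapped)
  structure(list(hits = hits, summary = smry,
                 metadata = c(bundle$metadata,
                              list(total_reads = total,
                                   mapped_reads = mapped,
                                   zero_mapped = mapped == 0L))),
            class = "isomir_profile")
}

profile_summary <- function(hits, total, mapped) {
  count_of <- function(idx) sum(hits$count[idx])
  n_excl <- count_of(hits$category != "variant" & hits$exclusive %in% "Y")
  n_ambg <- count_of(hits$category != "variant" & hits$exclusive %in% "N")
  n_var <- count_of(hits$category == "variant")
  n_nta <- count_of(hits$category == "nta")
  pct <- function(x) if (total > 0) 100 * x / total else 0
  tibble(
    total_reads = total,
    mapped_reads = mapped,
    exclusive_reads = n_excl,
    ambiguous_reads = n_ambg,
    variant_reads = n_var,
    nta_reads = n_nta,
    unmapped_reads = total - mapped,
    pct_exclusive = pct(n_excl),
    pct_ambiguous = pct(n_ambg),
    pct_variant = pct(n_var),
    pct_nta = pct(n_nta),
    pct_unmapped = pct(total - mapped))
}

#' @export
print.isomir_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<isomir_profile> %d reads, %d mapped (%.1f%%)\n",
              s$total_reads, s$mapped_reads,
              ifelse(s$total_reads > 0, 100 * s$mapped_reads / s$total_reads, 0)))
  cat(sprintf("  exclusive %d | ambiguous %d | variant %d | NTA-rescued %d | unmapped %d\n",
              s$exclusive_reads, s$ambiguous_reads, s$variant_reads,
              s$nta_reads, s$unmapped_reads))
  cat(sprintf("  distinct isomiRs reported: %d\n", nrow(x$hits)))
  invisible(x)
}

#' Tidy an isomiR profile
#'
#' `tidy()` returns the per-isomiR hit table; `glance()` the one-row run
#' summary.
#'
#' @param x An `isomir_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy isomir_profile
#' @export
tidy.isomir_profile <- function(x, ...) {
  as_tibble(x$hits)
}

#' @rdname tidy.isomir_profile
#' @method glance isomir_profile
#' @export
glance.isomir_profile <- function(x, ...) {
  x$summary
}
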