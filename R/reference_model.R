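# Reference model: genome + precursor/mature annotations, flank expansion,
# and the naming schemes (offset labels, genome-anchored labels).
#
# Annotation input is a documented tab-separated dialect rather than native
# miRBase GFF3 / miRCarta dumps; the columns are exactly those the model
# needs and converters from database dumps are one-liners in any scripting
# language.

REQUIRED_PRECURSOR_COLS <- c("name", "db", "chrom", "strand", "start", "end")
REQUIRED_MATURE_COLS <- c("precursor", "name", "offset", "length")

#' Read a genome from FASTA
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] with uppercase sequences; names are
#'   truncated at the first whitespace, and must be unique.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names in ", path, call. = FALSE)
  }
  if (any(Biostrings::width(genome) == 0L)) {
    stop("empty sequence in ", path, call. = FALSE)
  }
  Biostrings::DNAStringSet(toupper(genome))
}

#' Read precursor and mature annotation tables
#'
#' The precursor table is tab-separated with columns `name`, `db` (one of
#' `mirbase`, `mircarta`, `other`), `chrom`, `strand` (`+`/`-`), `start`,
#' `end` (1-based inclusive genomic coordinates of the unexpanded hairpin).
#' The mature table has columns `precursor`, `name`, `offset` (1-based start
#' of the mature reference within the unexpanded precursor, in precursor
#' orientation) and `length`.
#'
#' @param path Path to a tab-separated annotation file with a header line.
#' @return A tibble with the validated columns.
#' @export
read_precursors <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         .default = readr::col_character()))
  validate_precursors(x)
}

#' @rdname read_precursors
#' @export
read_matures <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         offset = readr::col_integer(),
                         length = readr::col_integer(),
                         .default = readr::col_character()))
  validate_matures(x)
}

validate_precursors <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(REQUIRED_PRECURSOR_COLS, names(x))
  if (length(missing) > 0) {
    stop("precursor table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$db %in% c("mirbase", "mircarta", "other"))) {
    stop("precursor db must be one of mirbase/mircarta/other", call. = FALSE)
  }
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be + or -", call. = FALSE)
  if (any(x$start > x$end)) stop("precursor start > end", call. = FALSE)
  if (anyDuplicated(x$name)) stop("duplicate precursor names", call. = FALSE)
  x
}

validate_matures <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(REQUIRED_MATURE_COLS, names(x))
  if (length(missing) > 0) {
    stop("mature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$offset < 1L) || any(x$length < 1L)) {
    stop("mature offset and length must be >= 1", call. = FALSE)
  }
  x
}

#' Expand precursors with genomic flanks
#'
#' Pads each precursor with `flank` nucleotides of genomic context on both
#' sides, in precursor orientation, and extracts the strand-oriented
#' sequence. The flanks admit isomiRs that extend past the annotated hairpin
#' boundaries (truncated database entries, unannotated arms). A flank that
#' would run past a chromosome end is clipped with a warning and the actual
#' pads recorded, so coordinate arithmetic downstream stays exact.
#'
#' @param precursors Precursor tibble (see [read_precursors()]).
#' @param genome A [Biostrings::DNAStringSet] holding the chromosomes.
#' @param flank Nucleotides of padding on each side (default 6).
#' @return A tibble with one row per precursor: the input columns plus
#'   `gstart`/`gend` (expanded genomic span, ascending coordinates), `pad5`/
#'   `pad3` (realised flank on the precursor 5'/3' side), `seq` (expanded
#'   strand-oriented sequence) and `length`.
#' @export
expand_precursors <- function(precursors, genome, flank = 6L) {
  precursors <- validate_precursors(precursors)
  stopifnot(flank >= 0L)
  missing_chrom <- setdiff(unique(precursors$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- precursors |>
    mutate(
      gstart = pmax(1L, .data$start - as.integer(flank)),
      gend = pmin(unname(chrom_len[.data$chrom]), .data$end + as.integer(flank)),
      pad_left = .data$start - .data$gstart,
      pad_right = .data$gend - .data$end,
      pad5 = ifelse(.data$strand == "+", .data$pad_left, .data$pad_right),
      pad3 = ifelse(.data$strand == "+", .data$pad_right, .data$pad_left),
      flank = as.integer(flank)
    ) |>
    select(-"pad_left", -"pad_right")
  clipped <- out$pad5 < flank | out$pad3 < flank
  if (any(clipped)) {
    warning("flank clipped at chromosome edge for: ",
            paste(out$name[clipped], collapse = ", "), call. = FALSE)
  }
  slices <- Biostrings::DNAStringSet(genome[out$chrom],
                                     start = out$gstart, end = out$gend)
  neg <- out$strand == "-"
  slices[neg] <- Biostrings::reverseComplement(slices[neg])
  out$seq <- unname(as.character(slices))
  out$length <- nchar(out$seq)
  out
}

#' Map expanded-precursor positions to genomic coordinates
#'
#' Position 1 of an expanded precursor is its 5'-most base in precursor
#' orientation: the left end of the genomic span on `+`, the right end on
#' `-`. The mapping is a bijection between 1..length and the genomic span.
#'
#' @param expanded One row of an [expand_precursors()] tibble.
#' @param pos Integer vector of 1-based positions in the expanded sequence.
#' @return Integer vector of genomic coordinates.
#' @export
expanded_to_genomic <- function(expanded, pos) {
  stopifnot(nrow(expanded) == 1L, all(pos >= 1L), all(pos <= expanded$length))
  if (expanded$strand == "+") expanded$gstart + pos - 1L else expanded$gend - pos + 1L
}

#' @rdname expanded_to_genomic
#' @param gpos Integer vector of genomic coordinates within the expanded span.
#' @export
genomic_to_expanded <- function(expanded, gpos) {
  stopifnot(nrow(expanded) == 1L,
            all(gpos >= expanded$gstart), all(gpos <= expanded$gend))
  if (expanded$strand == "+") gpos - expanded$gstart + 1L else expanded$gend - gpos + 1L
}

#' Offset labels for isomiRs
#'
#' The offset label `name|d5|d3` states how an isomiR's endpoints differ from
#' a database's mature reference: `d5` is the signed shift of the isomiR
#' 5' start relative to the reference 5' start and `d3` the shift of its 3'
#' end relative to the reference 3' end, both measured in precursor
#' orientation. Negative values point upstream (toward the 5' end of the
#' precursor). A reference-identical isomiR is `name|0|0`.
#'
#' @param mature_name Mature reference name(s).
#' @param d5,d3 Integer endpoint shifts.
#' @return Character vector of labels.
#' @export
offset_label <- function(mature_name, d5, d3) {
  sprintf("%s|%d|%d", mature_name, as.integer(d5), as.integer(d3))
}

#' Genome-anchored ("WithFlank") labels
#'
#' A genome-assembly-dependent name of the form
#' `precursor&WithFlank&chrom|strand|gstart|gend@start.end.length`, anchoring
#' an isomiR to a flank-padded precursor: `gstart`/`gend` are the expanded
#' precursor's genomic span (ascending), and `start`/`end` are the isomiR's
#' 1-based inclusive positions within the expanded, strand-oriented
#' sequence, followed by its length.
#'
#' @param expanded Expanded precursor tibble rows (recycled against
#'   `start`/`length`).
#' @param start 1-based start position(s) in the expanded sequence.
#' @param length isomiR length(s) in nucleotides.
#' @return Character vector of labels.
#' @export
genome_label <- function(expanded, start, length) {
  start <- as.integer(start)
  length <- as.integer(length)
  stopifnot(all(start >= 1L), all(start + length - 1L <= expanded$length))
  sprintf("%s&WithFlank&%s|%s|%d|%d@%d.%d.%d",
          expanded$name, expanded$chrom, expanded$strand,
          expanded$gstart, expanded$gend,
          start, start + length - 1L, length)
}

#' Offset labels against every overlapping mature reference
#'
#' For a set of placements (positions of a sequence inside expanded
#' precursors), computes one offset label per (database, mature reference)
#' whose span the placement overlaps. Databases are reported side by side
#' and never reconciled: where miRBase and miRCarta disagree about the
#' mature endpoints, the same molecule legitimately carries a different
#' offset label under each.
#'
#' @param placements Tibble with columns `precursor`, `start`, `length`
#'   (expanded-precursor coordinates).
#' @param expanded Tibble from [expand_precursors()].
#' @param matures Mature reference tibble (see [read_matures()]).
#' @return A tibble with columns `precursor`, `start`, `length`, `db`,
#'   `mature`, `d5`, `d3`, `label`; zero rows for placements overlapping no
#'   mature.
#' @export
alternative_labels <- function(placements, expanded, matures) {
  matures <- validate_matures(matures)
  exp_min <- expanded |> select("name", "db", "pad5")
  m <- matures |>
    left_join(exp_min, by = c("precursor" = "name")) |>
    mutate(m_start = .data$offset + .data$pad5,
           m_end = .data$m_start + .data$length - 1L) |>
    select(precursor = "precursor", db = "db", mature = "name",
           m_start = "m_start", m_end = "m_end")
  placements |>
    select("precursor", "start", "length") |>
    mutate(end = .data$start + .data$length - 1L) |>
    left_join(m, by = "precursor", relationship = "many-to-many") |>
    filter(!is.na(.data$mature),
           .data$start <= .data$m_end, .data$end >= .data$m_start) |>
    mutate(d5 = .data$start - .data$m_start,
           d3 = .data$end - .data$m_end,
           label = offset_label(.data$mature, .data$d5, .data$d3)) |>
    select("precursor", "start", "length", "db", "mature", "d5", "d3", "label")
}
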