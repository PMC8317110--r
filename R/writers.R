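# Output assembly and the three result formats. One output row per distinct
# reported sequence; all placements and labels for that sequence live on the
# same row (delimited lists), so abundances are never repeated across
# placements and cannot be multi-counted downstream.

#' Assemble the full per-isomiR output rows
#'
#' Joins each hit with all of its precursor placements, offset labels under
#' every loaded database, and genome-anchored labels. Wild-type and NTA
#' rows carry exclusivity and repeat classes; variant rows carry variant
#' identifiers instead (neither exclusivity nor repeat overlap is defined
#' for them, since their sequence is absent from the genome). For NTA rows
#' the placements are those of the templated core and the `type` field
#' records the added base and tail length (e.g. `nta:A3`).
#'
#' @param profile An `isomir_profile` from [profile_reads()].
#' @param bundle The `isomir_bundle` the profile was computed against.
#' @return A tibble with one row per reported sequence, ordered by category
#'   then license plate.
#' @export
assemble_rows <- function(profile, bundle) {
  stopifnot(inherits(profile, "isomir_profile"),
            inherits(bundle, "isomir_bundle"))
  hits <- profile$hits
  if (nrow(hits) == 0L) {
    return(tibble(plate = character(), seq = character(),
                  templated_core = character(), category = character(),
                  type = character(), exclusive = character(),
                  repeat_classes = character(), placements = character(),
                  offset_labels = character(), genome_labels = character(),
                  variant_ids = character(), count = integer(),
                  rpm_all = double(), rpm_mapped = double()))
  }
  all_plc <- bind_rows(
    bundle$placements |> mutate(.table = "wildtype"),
    bundle$variant_placements |> mutate(.table = "variant"))
  lab <- alternative_labels(all_plc, bundle$expanded, bundle$matures)
  lab_by_plc <- lab |>
    group_by(.data$precursor, .data$start, .data$length) |>
    summarise(offset_labels = paste(
      unique(paste0(.data$db, ":", .data$label)), collapse = ";"),
      .groups = "drop")
  exp_by_name <- split(seq_len(nrow(bundle$expanded)), bundle$expanded$name)
  plc_ann <- all_plc |>
    left_join(lab_by_plc, by = c("precursor", "start", "length")) |>
    mutate(offset_labels = ifelse(is.na(.data$offset_labels), "",
                                  .data$offset_labels))
  plc_ann$genome_label <- vapply(seq_len(nrow(plc_ann)), function(i) {
    e <- bundle$expanded[exp_by_name[[plc_ann$precursor[i]]], ]
    genome_label(e, plc_ann$start[i], plc_ann$length[i])
  }, character(1))
  plc_by_seq <- plc_ann |>
    arrange(.data$precursor, .data$start) |>
    group_by(.data$seq) |>
    summarise(
      placements = paste(sprintf("%s@%d.%d", .data$precursor, .data$start,
                                 .data$start + .data$length - 1L),
                         collapse = ";"),
      offset_labels = paste(
        unique(.data$offset_labels[nzchar(.data$offset_labels)]),
        collapse = ";"),
      genome_labels = paste(.data$genome_label, collapse = ";"),
      .groups = "drop")
  hits |>
    mutate(lookup_seq = ifelse(.data$category == "nta",
                               .data$templated_core, .data$seq),
           type = dplyr::case_when(
             category == "nta" ~ sprintf("nta:%s%d",
                                         substr(tail, 1L, 1L), nchar(tail)),
             category == "variant" ~ "variant",
             TRUE ~ "wildtype")) |>
    left_join(plc_by_seq, by = c(lookup_seq = "seq")) |>
    mutate(exclusive = ifelse(is.na(.data$exclusive), "", .data$exclusive),
           repeat_classes = ifelse(is.na(.data$repeat_classes), "",
                                   .data$repeat_classes),
           variant_ids = ifelse(is.na(.data$variant_ids), "",
                                .data$variant_ids)) |>
    select("plate", "seq", "templated_core", "category", "type", "exclusive",
           "repeat_classes", "placements", "offset_labels", "genome_labels",
           "variant_ids", "count", "rpm_all", "rpm_mapped") |>
    arrange(.data$category, .data$plate)
}

summary_block <- function(summary) {
  c(sprintf("# total_reads\t%d", summary$total_reads),
    sprintf("# mapped_reads\t%d", summary$mapped_reads),
    sprintf("# exclusive_reads\t%d\t%.4f%%", summary$exclusive_reads,
            summary$pct_exclusive),
    sprintf("# ambiguous_reads\t%d\t%.4f%%", summary$ambiguous_reads,
            summary$pct_ambiguous),
    sprintf("# variant_reads\t%d\t%.4f%%", summary$variant_reads,
            summary$pct_variant),
    sprintf("# nta_reads\t%d\t%.4f%%", summary$nta_reads, summary$pct_nta),
    sprintf("# unmapped_reads\t%d\t%.4f%%", summary$unmapped_reads,
            summary$pct_unmapped))
}

#' Write the tab-separated results
#'
#' Writes `<prefix>.isomirs.tsv` (wild-type and NTA rows) and
#' `<prefix>.variants.tsv` (variant rows, reported separately). Each file
#' starts with a commented summary block, then a header line and one row
#' per distinct sequence in deterministic order (category, then license
#' plate). [read_profile_tsv()] parses the files back losslessly.
#'
#' @param profile An `isomir_profile`.
#' @param bundle The matching `isomir_bundle`.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_profile_tsv <- function(profile, bundle, prefix) {
  rows <- assemble_rows(profile, bundle)
  blk <- summary_block(profile$summary)
  write_one <- function(rows, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(blk, con)
    writeLines(paste(names(rows), collapse = "\t"), con)
    if (nrow(rows) > 0L) {
      body <- do.call(paste, c(lapply(rows, format_tsv_field), sep = "\t"))
      writeLines(body, con)
    }
  }
  paths <- paste0(prefix, c(".isomirs.tsv", ".variants.tsv"))
  write_one(rows |> filter(.data$category != "variant"), paths[1])
  write_one(rows |> filter(.data$category == "variant"), paths[2])
  invisible(paths)
}

format_tsv_field <- function(x) {
  if (is.double(x)) sprintf("%.6f", x) else as.character(x)
}

#' @rdname write_profile_tsv
#' @param path Path of one file written by `write_profile_tsv()`.
#' @return `read_profile_tsv()` returns a list with `rows` (tibble) and
#'   `summary` (tibble parsed from the comment block).
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  smry_lines <- grep("^# ", lines, value = TRUE)
  smry_parts <- str_split(sub("^# ", "", smry_lines), "\t")
  smry <- tibble(
    field = vapply(smry_parts, `[`, character(1), 1L),
    count = as.integer(vapply(smry_parts, `[`, character(1), 2L)),
    pct = vapply(smry_parts, function(p) {
      if (length(p) >= 3L) as.numeric(sub("%$", "", p[3])) else NA_real_
    }, numeric(1)))
  rows <- readr::read_tsv(path, comment = "# ", show_col_types = FALSE,
                          na = character(),
                          col_types = readr::cols(
                            count = "i", rpm_all = "d", rpm_mapped = "d",
                            .default = readr::col_character()))
  list(rows = as_tibble(rows), summary = smry)
}

#' Write mirGFF3 output
#'
#' One GFF3 feature line per (reported sequence, precursor placement). The
#' seqid is the precursor name; coordinates are given on the unexpanded
#' precursor when the isomiR lies fully inside it, otherwise on the
#' flank-padded precursor under its `WithFlank` name. Attributes follow the
#' mirGFF3 controlled vocabulary: `UID` (license plate), `Read`, `Name`,
#' `Parent`, `Variant` (`iso_5p`/`iso_3p` endpoint shifts, `iso_add3p` for
#' non-templated tails, `iso_snv` for variant-containing sequences; `NA`
#' for a reference-identical molecule), `Expression` (raw count) and
#' `Filter`. Sign convention: `iso_5p:+n` means the 5' end starts `n` nt
#' upstream of the reference 5' end, `iso_3p:+n` means the 3' end extends
#' `n` nt downstream of the reference 3' end.
#'
#' @param profile An `isomir_profile`.
#' @param bundle The matching `isomir_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_gff3 <- function(profile, bundle, path) {
  hits <- profile$hits
  lab <- alternative_labels(
    bind_rows(bundle$placements, bundle$variant_placements),
    bundle$expanded, bundle$matures)
  lines <- c("##gff-version 3",
             sprintf("# source: isomirs (%s / %s)",
                     bundle$metadata$reference_set, bundle$metadata$genome_tag))
  if (nrow(hits) > 0L) {
    plc <- bind_rows(bundle$placements, bundle$variant_placements)
    exp_ix <- split(seq_len(nrow(bundle$expanded)), bundle$expanded$name)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      lk <- if (h$category == "nta") h$templated_core else h$seq
      p <- plc |> filter(.data$seq == lk)
      for (j in seq_len(nrow(p))) {
        e <- bundle$expanded[exp_ix[[p$precursor[j]]], ]
        s_exp <- p$start[j]
        e_exp <- s_exp + p$length[j] - 1L
        s_un <- s_exp - e$pad5
        e_un <- e_exp - e$pad5
        un_len <- e$end - e$start + 1L
        if (s_un >= 1L && e_un <= un_len) {
          seqid <- e$name
          s_out <- s_un
          e_out <- e_un
        } else {
          seqid <- sprintf("%s&WithFlank", e$name)
          s_out <- s_exp
          e_out <- e_exp
        }
        l <- lab |>
          filter(.data$precursor == p$precursor[j],
                 .data$start == p$start[j], .data$length == p$length[j])
        nm <- if (nrow(l) > 0L) l$label[1] else sprintf("%s@%d.%d", e$name,
                                                        s_exp, e_exp)
        vterms <- character(0)
        if (nrow(l) > 0L) {
          if (l$d5[1] != 0L) {
            vterms <- c(vterms, sprintf("iso_5p:%+d", -l$d5[1]))
          }
          if (l$d3[1] != 0L) {
            vterms <- c(vterms, sprintf("iso_3p:%+d", l$d3[1]))
          }
        }
        if (h$category == "nta") {
          vterms <- c(vterms, sprintf("iso_add3p:%d", nchar(h$tail)))
        }
        if (h$category == "variant") vterms <- c(vterms, "iso_snv")
        variant_attr <- if (length(vterms) == 0L) "NA" else
          paste(vterms, collapse = ",")
        ftype <- if (identical(variant_attr, "NA")) "ref_miRNA" else "isomiR"
        attrs <- sprintf(
          "UID=%s;Read=%s;Name=%s;Parent=%s;Variant=%s;Expression=%d;Filter=Pass",
          h$plate, h$seq, nm, e$name, variant_attr, h$count)
        lines <- c(lines, paste(seqid, "isomirs", ftype, s_out, e_out,
                                ".", e$strand, ".", attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
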