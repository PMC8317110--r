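# LookupTableBundle: the product of the offline build, everything the online
# profiler needs. Serialized as versioned, diffable tab-separated files plus
# a JSON metadata sidecar, so tables can be inspected and amended by hand.

BUNDLE_FORMAT_VERSION <- "1"

#' Build the k-mer lookup tables for a reference set
#'
#' Runs the whole offline stage: enumerates candidate isomiRs from the
#' flank-expanded precursors, finds every genomic instance of every
#' candidate, classifies each as exclusive to miRNA-space or ambiguous,
#' attaches repeat-class attributes, and (when variants are supplied)
#' precomputes the variant k-mer table. The result is self-contained: the
#' profiler never touches the genome.
#'
#' @param precursors Precursor tibble (see [read_precursors()]).
#' @param matures Mature reference tibble (see [read_matures()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @param repeats Optional repeat interval tibble (see [read_repeats()]).
#' @param variants Optional variant tibble (see [read_variants()]).
#' @param flank Flank size in nucleotides (default 6).
#' @param kmin,kmax Candidate isomiR length bounds (defaults 18, 26).
#' @param reference_set Tag naming the miRNA reference set.
#' @param genome_tag Tag naming the genome build.
#' @return An object of class `isomir_bundle`: a list with tibbles
#'   `wildtype` (`seq`, `exclusive`, `repeat_classes`), `placements`,
#'   `instances`, `variant` (`seq`, `templated_seq`, `variant_ids`),
#'   `variant_placements`, plus `expanded`, `matures` and `metadata`.
#' @export
build_bundle <- function(precursors, matures, genome, repeats = NULL,
                         variants = NULL, flank = 6L, kmin = 18L, kmax = 26L,
                         reference_set = "custom", genome_tag = "custom") {
  matures <- validate_matures(matures)
  expanded <- expand_precursors(precursors, genome, flank = flank)
  cand <- enumerate_candidates(expanded, kmin = kmin, kmax = kmax)
  keys <- unique(cand$seq)
  inst <- find_genomic_instances(keys, genome)
  space <- mirna_space(expanded)
  if (!all(keys %in% inst$seq)) {
    stop("table k-mer(s) with no genomic instance; genome and precursor ",
         "annotations disagree", call. = FALSE)
  }
  excl <- if (length(keys) == 0L) {
    tibble(seq = character(), exclusive = character())
  } else {
    classify_exclusivity(inst, space)
  }
  reps <- if (is.null(repeats) || length(keys) == 0L) {
    tibble(seq = keys, repeat_classes = character(length(keys)))
  } else {
    annotate_repeats(inst, repeats)
  }
  wildtype <- tibble(seq = keys) |>
    left_join(excl, by = "seq") |>
    left_join(reps, by = "seq") |>
    arrange(.data$seq)
  var <- if (is.null(variants)) {
    list(table = tibble(seq = character(), templated_seq = character(),
                        variant_ids = character()),
         placements = tibble(seq = character(), precursor = character(),
                             start = integer(), length = integer()))
  } else {
    build_variant_table(expanded, variants, genome, keys,
                        kmin = kmin, kmax = kmax)
  }
  inst$in_mirna_space <- instance_in_space(inst, space)
  structure(list(
    wildtype = wildtype,
    placements = cand,
    instances = inst,
    variant = var$table |> arrange(.data$seq),
    variant_placements = var$placements,
    expanded = expanded |> arrange(.data$name),
    matures = matures |> arrange(.data$precursor, .data$name),
    metadata = list(format_version = BUNDLE_FORMAT_VERSION,
                    reference_set = reference_set, genome_tag = genome_tag,
                    flank = as.integer(flank), kmin = as.integer(kmin),
                    kmax = as.integer(kmax))
  ), class = "isomir_bundle")
}

#' @export
print.isomir_bundle <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<isomir_bundle> %s / %s (flank %d, k %d-%d)\n", m$reference_set,
    m$genome_tag, m$flank, m$kmin, m$kmax))
  cat(sprintf("  wild-type k-mers: %d (%d placements, %d genomic instances)\n",
              nrow(x$wildtype), nrow(x$placements), nrow(x$instances)))
  cat(sprintf("  variant k-mers:   %d\n", nrow(x$variant)))
  invisible(x)
}

bundle_files <- c(
  wildtype = "wildtype_kmers.tsv", placements = "placements.tsv",
  instances = "instances.tsv", variant = "variant_kmers.tsv",
  variant_placements = "variant_placements.tsv", expanded = "precursors.tsv",
  matures = "matures.tsv")

#' Serialize / load a lookup-table bundle
#'
#' The bundle directory holds one tab-separated file per table plus
#' `metadata.json`. Files are written in a canonical row order, so two
#' builds from identical inputs are byte-identical regardless of input file
#' ordering, and `load_bundle(serialize_bundle(b))` reproduces `b` exactly.
#'
#' @param bundle An `isomir_bundle`.
#' @param dir Directory to write into (created if needed).
#' @return `serialize_bundle()` returns `dir` invisibly; `load_bundle()`
#'   returns the bundle.
#' @export
serialize_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "isomir_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle_files)) {
    readr::write_tsv(bundle[[nm]], file.path(dir, bundle_files[[nm]]))
  }
  jsonlite::write_json(bundle$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname serialize_bundle
#' @export
load_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) {
    stop("not a bundle directory (metadata.json missing): ", dir,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), BUNDLE_FORMAT_VERSION)) {
    stop("bundle format version ", meta$format_version,
         " is not supported (expected ", BUNDLE_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  col_specs <- list(
    wildtype = readr::cols(seq = "c", exclusive = "c", repeat_classes = "c"),
    placements = readr::cols(seq = "c", precursor = "c", start = "i",
                             length = "i"),
    instances = readr::cols(seq = "c", chrom = "c", strand = "c",
                            start = "i", end = "i", in_mirna_space = "l"),
    variant = readr::cols(seq = "c", templated_seq = "c", variant_ids = "c"),
    variant_placements = readr::cols(seq = "c", precursor = "c",
                                     start = "i", length = "i"),
    expanded = readr::cols(name = "c", db = "c", chrom = "c", strand = "c",
                           start = "i", end = "i", gstart = "i", gend = "i",
                           pad5 = "i", pad3 = "i", flank = "i", seq = "c",
                           length = "i"),
    matures = readr::cols(precursor = "c", name = "c", offset = "i",
                          length = "i"))
  out <- purrr::imap(bundle_files, function(f, nm) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("bundle file missing: ", f, call. = FALSE)
    readr::read_tsv(path, col_types = col_specs[[nm]], na = character(),
                    progress = FALSE)
  })
  out$metadata <- list(format_version = as.character(meta$format_version),
                       reference_set = meta$reference_set,
                       genome_tag = meta$genome_tag,
                       flank = as.integer(meta$flank),
                       kmin = as.integer(meta$kmin),
                       kmax = as.integer(meta$kmax))
  overlap <- intersect(out$wildtype$seq, out$variant$seq)
  if (length(overlap) > 0L) {
    stop("corrupt bundle: wild-type and variant tables share keys",
         call. = FALSE)
  }
  structure(out, class = "isomir_bundle")
}
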