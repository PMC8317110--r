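# Shared fixture objects, built once per test run, plus the independent
# brute-force oracles the k-mer machinery is held to.

fx_ref <- make_reference()
fx_bundle <- build_bundle(fx_ref$precursors, fx_ref$matures, fx_ref$genome,
                          fx_ref$repeats, fx_ref$variants,
                          reference_set = "synthetic", genome_tag = "mini")
fx_recipe <- default_read_recipe(fx_ref, fx_bundle)

fx_fastq <- tempfile(fileext = ".fastq")
simulate_reads(fx_recipe, fx_fastq, seed = 7L)
fx_profile <- profile_reads(fx_fastq, fx_bundle)

# quadratic scanning oracle: every exact occurrence of every query on both
# strands, by direct position-by-position substring comparison
oracle_scan_genome <- function(seqs, genome) {
  seqs <- unique(seqs)
  g <- as.character(genome)
  out <- list()
  for (k in sort(unique(nchar(seqs)))) {
    qs <- seqs[nchar(seqs) == k]
    qr <- revcomp(qs)
    for (ch in names(g)) {
      n <- nchar(g[[ch]])
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      subs <- substring(g[[ch]], starts, starts + k - 1L)
      fwd <- which(subs %in% qs)
      rev <- which(subs %in% qr)
      if (length(fwd) > 0L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          seq = subs[fwd], chrom = ch, strand = "+",
          start = starts[fwd], end = starts[fwd] + k - 1L)
      }
      if (length(rev) > 0L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          seq = qs[match(subs[rev], qr)], chrom = ch, strand = "-",
          start = starts[rev], end = starts[rev] + k - 1L)
      }
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(seq, chrom, start, strand)
}

# nested-loop substring oracle for candidate enumeration
oracle_enumerate <- function(expanded, kmin, kmax) {
  rows <- list()
  for (i in seq_len(nrow(expanded))) {
    s <- expanded$seq[i]
    for (k in kmin:kmax) {
      if (nchar(s) < k) next
      for (st in seq_len(nchar(s) - k + 1L)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          seq = substr(s, st, st + k - 1L), precursor = expanded$name[i],
          start = st, length = k)
      }
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::filter(!grepl("N", seq)) |>
    dplyr::arrange(seq, precursor, start)
}

# interval-containment oracle for exclusivity: all instances within some
# space interval?
oracle_exclusive <- function(instances, space) {
  per <- vapply(seq_len(nrow(instances)), function(i) {
    any(space$chrom == instances$chrom[i] &
          space$start <= instances$start[i] &
          instances$end[i] <= space$end)
  }, logical(1))
  res <- tapply(per, instances$seq, all)
  stats::setNames(as.logical(res), names(res))
}

# all-pairs containment oracle for repeat classes
oracle_repeats <- function(instances, repeats) {
  out <- character(0)
  for (i in seq_len(nrow(instances))) {
    for (j in seq_len(nrow(repeats))) {
      if (instances$chrom[i] == repeats$chrom[j] &&
          repeats$start[j] <= instances$start[i] &&
          instances$end[i] <= repeats$end[j]) {
        out <- c(out, repeats$class[j])
      }
    }
  }
  sort(unique(out))
}

# string-mutation oracle for the variant table: apply each kept variant to
# each expanded precursor sequence it falls in and enumerate all substrings
# in the k range that are not wild-type keys
oracle_variant_seqs <- function(expanded, variants, wildtype_seqs,
                                kmin, kmax) {
  kept <- variants[variants$source == "COSMIC" |
                     (!is.na(variants$max_af) & variants$max_af >= 0.01), ]
  out <- character(0)
  for (vi in seq_len(nrow(kept))) {
    v <- kept[vi, ]
    # genomic edit applied on the forward strand of the genomic slice
    for (pi in seq_len(nrow(expanded))) {
      e <- expanded[pi, ]
      if (e$chrom != v$chrom) next
      gpos_edit <- if (nchar(v$ref) > nchar(v$alt)) v$pos + 1L else v$pos
      if (gpos_edit < e$gstart || gpos_edit > e$gend) next
      fwd <- if (e$strand == "+") e$seq else revcomp(e$seq)
      off <- v$pos - e$gstart + 1L
      if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
        edited <- paste0(substr(fwd, 1L, off - 1L), v$alt,
                         substr(fwd, off + 1L, nchar(fwd)))
      } else if (nchar(v$alt) > nchar(v$ref)) {
        edited <- paste0(substr(fwd, 1L, off), substr(v$alt, 2L, 2L),
                         substr(fwd, off + 1L, nchar(fwd)))
      } else {
        edited <- paste0(substr(fwd, 1L, off), substr(fwd, off + 2L,
                                                      nchar(fwd)))
      }
      oriented <- if (e$strand == "+") edited else revcomp(edited)
      for (k in kmin:kmax) {
        if (nchar(oriented) < k) next
        for (st in seq_len(nchar(oriented) - k + 1L)) {
          out <- c(out, substr(oriented, st, st + k - 1L))
        }
      }
    }
  }
  sort(setdiff(unique(out), wildtype_seqs))
}
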