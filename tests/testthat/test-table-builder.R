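test_that("candidate enumeration matches the substring-counting formula", {
  # one 72-nt expanded precursor: sum over k of (72 - k + 1) placements
  e1 <- fx_bundle$expanded[fx_bundle$expanded$name == "syn-mir-1", ]
  cand <- enumerate_candidates(e1, kmin = 18L, kmax = 26L)
  expect_identical(nrow(cand), sum(72L - 18:26 + 1L))
  expect_identical(nrow(cand), 459L)
})

test_that("candidate enumeration equals the nested-loop oracle", {
  sub_exp <- fx_bundle$expanded[fx_bundle$expanded$name %in%
                                  c("syn-mir-3", "syn-mir-4"), ]
  got <- enumerate_candidates(sub_exp, 18L, 26L)
  expect_identical(as.data.frame(got),
                   as.data.frame(oracle_enumerate(sub_exp, 18L, 26L)))
  # a sequence shared by the overlapping pair is keyed with both placements
  shared <- got |> dplyr::count(seq) |> dplyr::filter(n >= 2L)
  expect_gt(nrow(shared), 0L)
})

test_that("N-containing substrings are excluded from enumeration", {
  e <- tibble::tibble(name = "p", seq = paste0(strrep("A", 20), "N",
                                               strrep("C", 20)))
  cand <- enumerate_candidates(e, 18L, 26L)
  expect_false(any(grepl("N", cand$seq)))
  expect_true(all(cand$start + cand$length - 1L <= 20L | cand$start >= 22L))
})

test_that("genomic instance search equals the quadratic scanning oracle", {
  # decoy sequence: one source locus plus two planted copies
  d <- fx_ref$truth$decoys
  got <- find_genomic_instances(d$seq[1], fx_ref$genome)
  expect_identical(nrow(got), 3L)
  expect_identical(as.data.frame(got),
                   as.data.frame(oracle_scan_genome(d$seq[1], fx_ref$genome)))
  # absent sequence
  expect_identical(nrow(find_genomic_instances(strrep("ACGT", 5),
                                               fx_ref$genome)), 0L)
  # overlapping occurrences are all reported
  g <- Biostrings::DNAStringSet(c(c1 = paste0(strrep("AT", 15), "GGGG")))
  pat <- strrep("AT", 9)
  got2 <- find_genomic_instances(pat, g)
  orc2 <- oracle_scan_genome(pat, g)
  expect_identical(as.data.frame(got2), as.data.frame(orc2))
  expect_gt(nrow(got2), 2L)
})

test_that("exclusivity classification matches the containment oracle", {
  wt <- fx_bundle$wildtype
  inst <- fx_bundle$instances
  space <- mirna_space(fx_bundle$expanded)
  orc <- oracle_exclusive(inst, space)
  expect_identical(wt$exclusive,
                   unname(ifelse(orc[wt$seq], "Y", "N")))

  # the decoyed isomiR is ambiguous; both planted copies lie outside space
  expect_identical(wt$exclusive[wt$seq == fx_ref$truth$decoys$seq[1]], "N")
  # a k-mer whose only instance is its source locus is exclusive
  singles <- inst |> dplyr::count(seq) |> dplyr::filter(n == 1L)
  expect_true(all(wt$exclusive[wt$seq %in% singles$seq] == "Y"))
  expect_error(
    classify_exclusivity(
      tibble::tibble(seq = character(), chrom = character(),
                     start = integer(), end = integer()), space),
    "empty instance list")
})

test_that("every table k-mer has at least one genomic instance", {
  expect_setequal(unique(fx_bundle$wildtype$seq),
                  unique(fx_bundle$instances$seq))
})

test_that("repeat annotation requires containment and matches the oracle", {
  wt <- fx_bundle$wildtype
  inst <- fx_bundle$instances
  # decoyed isomiR sits inside planted LINE copies
  expect_identical(wt$repeat_classes[wt$seq == fx_ref$truth$decoys$seq[1]],
                   "LINE")
  # the Simple_repeat interval contains syn-mir-6 entirely, so exclusive
  # k-mers can carry a repeat class
  p6 <- fx_bundle$placements |> dplyr::filter(precursor == "syn-mir-6")
  p6w <- wt |> dplyr::filter(seq %in% p6$seq)
  expect_true(any(p6w$exclusive == "Y" & p6w$repeat_classes == "Simple_repeat"))
  # all-pairs oracle over a sample of table k-mers
  set.seed(11)
  sample_seqs <- sample(wt$seq, 60)
  for (s in sample_seqs) {
    orc <- oracle_repeats(inst |> dplyr::filter(seq == s), fx_ref$repeats)
    expect_identical(wt$repeat_classes[wt$seq == s],
                     paste(orc, collapse = ","))
  }
})

test_that("unknown repeat classes are rejected at load time", {
  bad <- fx_ref$repeats |> dplyr::mutate(class = replace(class, 1, "ALU"))
  expect_error(validate_repeats(bad), "unknown repeat class")
})

test_that("variant table applies the frequency gate and matches the oracle", {
  vt <- fx_bundle$variant
  ids <- unique(unlist(strsplit(vt$variant_ids, ",")))
  # the rare dbSNP variant is filtered; somatic and common ones are kept
  expect_false(any(grepl("rs9000002", ids)))
  expect_setequal(sub(".*:", "", ids), fx_ref$truth$variant_kept)
  # emitted sequence set equals the string-mutation oracle
  orc <- oracle_variant_seqs(fx_bundle$expanded, fx_ref$variants,
                             fx_bundle$wildtype$seq, 18L, 26L)
  expect_identical(sort(vt$seq), orc)
  # key sets of the two tables are disjoint
  expect_length(intersect(vt$seq, fx_bundle$wildtype$seq), 0L)
})

test_that("variant records differ from their template by one edit", {
  vt <- fx_bundle$variant |>
    dplyr::filter(!grepl(",", .data$templated_seq))
  lev <- mapply(function(a, b) as.integer(adist(a, b)), vt$seq,
                vt$templated_seq)
  expect_true(all(lev == 1L))
})

test_that("variant building rejects a ref allele that contradicts the genome", {
  v <- fx_ref$variants[1, ] |>
    dplyr::mutate(ref = ifelse(ref == "A", "C", "A"),
                  alt = ifelse(ref == "A", "G", "T"))
  expect_error(
    build_variant_table(fx_bundle$expanded, v, fx_ref$genome,
                        fx_bundle$wildtype$seq),
    "does not match the genome|does not match genome")
})

test_that("an empty variant list yields an empty variant table", {
  out <- build_variant_table(fx_bundle$expanded, fx_ref$variants[0, ],
                             fx_ref$genome, fx_bundle$wildtype$seq)
  expect_identical(nrow(out$table), 0L)
})

test_that("bundle serialization round-trips byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  serialize_bundle(fx_bundle, d1)
  b2 <- load_bundle(d1)
  serialize_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e7),
                     readBin(file.path(d2, f), "raw", n = 1e7))
  }
  expect_identical(b2$metadata, fx_bundle$metadata)
  expect_identical(as.data.frame(b2$wildtype),
                   as.data.frame(fx_bundle$wildtype))
})

test_that("tables are diffable: a hand-appended k-mer row survives reload", {
  d <- withr::local_tempdir()
  serialize_bundle(fx_bundle, d)
  extra <- paste0(strrep("ACGTT", 4), "\tY\t", "\n")
  cat(sprintf("%s\tY\t\n", strrep("ACGTT", 4)),
      file = file.path(d, "wildtype_kmers.tsv"), append = TRUE)
  b2 <- load_bundle(d)
  expect_true(strrep("ACGTT", 4) %in% b2$wildtype$seq)
})

test_that("bundle loading rejects version mismatch and truncation", {
  d <- withr::local_tempdir()
  serialize_bundle(fx_bundle, d)
  meta <- jsonlite::read_json(file.path(d, "metadata.json"))
  meta$format_version <- "99"
  jsonlite::write_json(meta, file.path(d, "metadata.json"),
                       auto_unbox = TRUE)
  expect_error(load_bundle(d), "format version")
  expect_error(load_bundle(tempfile()), "metadata.json missing")
  d2 <- withr::local_tempdir()
  serialize_bundle(fx_bundle, d2)
  unlink(file.path(d2, "instances.tsv"))
  expect_error(load_bundle(d2), "bundle file missing")
})

test_that("an empty precursor set yields a valid empty bundle", {
  b <- build_bundle(fx_ref$precursors[0, ], fx_ref$matures[0, ],
                    fx_ref$genome)
  expect_identical(nrow(b$wildtype), 0L)
  expect_identical(nrow(b$variant), 0L)
  d <- withr::local_tempdir()
  serialize_bundle(b, d)
  expect_identical(nrow(load_bundle(d)$wildtype), 0L)
})

test_that("builds are deterministic under input permutation", {
  perm <- withr::with_seed(3L, sample(nrow(fx_ref$precursors)))
  vperm <- withr::with_seed(4L, sample(nrow(fx_ref$variants)))
  b2 <- build_bundle(fx_ref$precursors[perm, ], fx_ref$matures,
                     fx_ref$genome, fx_ref$repeats[c(3, 1, 2, 5, 4), ],
                     fx_ref$variants[vperm, ],
                     reference_set = "synthetic", genome_tag = "mini")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  serialize_bundle(fx_bundle, d1)
  serialize_bundle(b2, d2)
  for (f in setdiff(list.files(d1), "precursors.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # precursor table rows are themselves canonically ordered
  expect_identical(readLines(file.path(d1, "precursors.tsv")),
                   readLines(file.path(d2, "precursors.tsv")))
})

test_that("shorter k-mers are never less ambiguous than longer ones", {
  wt <- fx_bundle$wildtype |>
    dplyr::mutate(k = nchar(seq)) |>
    dplyr::group_by(k) |>
    dplyr::summarise(frac_ambiguous = mean(exclusive == "N"))
  expect_true(all(diff(wt$frac_ambiguous) <= 1e-12))
})
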