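test_that("FASTQ loading collapses reads and tracks filtered ones", {
  d <- withr::local_tempdir()
  # empty file
  f0 <- file.path(d, "empty.fastq")
  writeLines(character(0), f0)
  t0 <- load_reads(f0)
  expect_identical(nrow(t0), 0L)
  expect_identical(attr(t0, "total_reads"), 0L)
  # one sequence repeated five times collapses to one row
  f1 <- file.path(d, "five.fastq")
  s <- strrep("ACGT", 5)
  writeLines(rep(c("@r", s, "+", strrep("I", 20)), 5), f1)
  t1 <- load_reads(f1)
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$count, 5L)
  # gzipped input
  fz <- file.path(d, "five.fastq.gz")
  con <- gzfile(fz, "wb")
  writeLines(rep(c("@r", s, "+", strrep("I", 20)), 5), con)
  close(con)
  expect_identical(load_reads(fz)$count, 5L)
  # malformed record
  fbad <- file.path(d, "bad.fastq")
  writeLines(c("@r", s, s, strrep("I", 20)), fbad)
  expect_error(load_reads(fbad), "malformed FASTQ")
  # N-containing and short reads are ineligible but counted
  tf <- read_frequency_table(c("ACGTNACGTACGTACGTACGT", "ACGTACGT", s, s))
  expect_identical(attr(tf, "total_reads"), 4L)
  expect_identical(attr(tf, "reads_with_n"), 1L)
  expect_identical(attr(tf, "reads_too_short"), 1L)
  expect_identical(sum(tf$count), 4L)
  expect_identical(tf$eligible[tf$seq == s], TRUE)
})

test_that("simulated per-sequence counts are recovered exactly", {
  tf <- load_reads(fx_fastq)
  expected <- fx_recipe |> dplyr::arrange(seq)
  expect_identical(tf$seq, expected$seq)
  expect_identical(tf$count, expected$count)
})

test_that("a read equal to a table key resolves with all its placements", {
  e3 <- fx_bundle$expanded[fx_bundle$expanded$name == "syn-mir-3", ]
  shared <- substr(e3$seq, 30L, 49L)
  hit <- resolve_read(shared, fx_bundle)
  expect_identical(hit$category, "wildtype")
  plc <- fx_bundle$placements |> dplyr::filter(seq == shared)
  expect_setequal(plc$precursor, c("syn-mir-3", "syn-mir-4"))
})

test_that("NTA rescue strips homopolymer tails with minimal trimming", {
  nta <- fx_recipe |> dplyr::filter(kind == "nta")
  for (i in seq_len(nrow(nta))) {
    hit <- resolve_read(nta$seq[i], fx_bundle)
    expect_identical(hit$category, "nta")
    expect_identical(hit$templated_core, nta$core[i])
    expect_identical(hit$tail, nta$tail[i])
    expect_identical(hit$seq, paste0(hit$templated_core, hit$tail))
  }
  # minimal trimming: when core+b is itself a table key, only the extra
  # base is attributed to addition (a variant-free precursor is used so the
  # probe cannot collide with the variant table)
  e1 <- fx_bundle$expanded[fx_bundle$expanded$name == "syn-mir-3", ]
  core20 <- substr(e1$seq, 16L, 35L)
  b <- substr(e1$seq, 36L, 36L)   # templated continuation, so core+b is a key
  read <- paste0(core20, b, b)
  if (!(read %in% fx_bundle$wildtype$seq) &&
      !(read %in% fx_bundle$variant$seq)) {
    hit <- resolve_read(read, fx_bundle)
    expect_identical(hit$category, "nta")
    expect_identical(hit$templated_core, paste0(core20, b))
    expect_identical(hit$tail, b)
  }
  # a 17-nt read is below kmin and unmapped
  expect_null(resolve_read(substr(e1$seq, 16L, 32L), fx_bundle))
})

test_that("reads longer than kmax are reachable only through NTA rescue", {
  e1 <- fx_bundle$expanded[fx_bundle$expanded$name == "syn-mir-1", ]
  core26 <- substr(e1$seq, 10L, 35L)
  expect_true(core26 %in% fx_bundle$wildtype$seq)
  nxt <- substr(e1$seq, 36L, 36L)
  tail_base <- setdiff(c("A", "C", "G", "T"), nxt)[1]
  read29 <- paste0(core26, strrep(tail_base, 3))
  hit <- resolve_read(read29, fx_bundle)
  expect_identical(hit$category, "nta")
  expect_identical(hit$templated_core, core26)
})

test_that("a variant-table read resolves as a variant hit with identifiers", {
  vseq <- fx_bundle$variant$seq[1]
  hit <- resolve_read(vseq, fx_bundle)
  expect_identical(hit$category, "variant")
  prof_row <- fx_profile$hits |> dplyr::filter(category == "variant")
  expect_true(all(nzchar(prof_row$variant_ids)))
  expect_true(all(grepl("^(dbSNP|gnomAD|COSMIC):",
                        unlist(strsplit(prof_row$variant_ids, ",")))))
})

test_that("variant hits carry no exclusivity or repeat annotation", {
  vr <- fx_profile$hits |> dplyr::filter(category == "variant")
  expect_gt(nrow(vr), 0L)
  expect_true(all(is.na(vr$exclusive)))
  expect_true(all(is.na(vr$repeat_classes)))
})

test_that("RPM normalization conserves totals", {
  # single mapped read in a one-read dataset
  one <- read_frequency_table(fx_bundle$wildtype$seq[1])
  p1 <- profile_reads(one, fx_bundle)
  expect_equal(p1$hits$rpm_all, 1e6)
  expect_equal(p1$summary$pct_exclusive +
                 p1$summary$pct_ambiguous, 100)
  # planted {10,30,60} over 100 reads, all mapped
  keys <- fx_bundle$wildtype$seq[c(1, 200, 400)]
  tf <- read_frequency_table(rep(keys, c(10L, 30L, 60L)))
  p2 <- profile_reads(tf, fx_bundle)
  expect_equal(sort(p2$hits$rpm_all), c(1e5, 3e5, 6e5))
  expect_equal(sum(p2$hits$rpm_mapped), 1e6)
  # on the full fixture too
  expect_equal(sum(fx_profile$hits$rpm_mapped), 1e6)
})

test_that("zero mapped reads give zero rpm_mapped, not NaN", {
  tf <- read_frequency_table(c(strrep("A", 17), strrep("ACGTN", 5)))
  p <- profile_reads(tf, fx_bundle)
  expect_identical(nrow(p$hits), 0L)
  expect_identical(p$summary$mapped_reads, 0L)
  expect_identical(p$summary$unmapped_reads, 2L)
  expect_true(p$metadata$zero_mapped)
})

test_that("category counts partition mapped reads", {
  s <- fx_profile$summary
  expect_identical(s$exclusive_reads + s$ambiguous_reads + s$variant_reads,
                   s$mapped_reads)
  expect_identical(s$mapped_reads + s$unmapped_reads, s$total_reads)
  expect_lte(s$pct_exclusive + s$pct_ambiguous + s$pct_variant +
               s$pct_unmapped, 100 + 1e-9)
  # NTA reads are counted inside exclusive/ambiguous, not alongside them
  nta_counts <- fx_profile$hits |>
    dplyr::filter(category == "nta") |>
    dplyr::pull(count)
  expect_identical(s$nta_reads, sum(nta_counts))
})

test_that("every planted read lands in its planted category with its count", {
  truth <- fx_recipe |>
    dplyr::mutate(kind = ifelse(kind == "junk" | kind == "filtered",
                                "unmapped", kind))
  hits <- fx_profile$hits
  mapped_truth <- truth |> dplyr::filter(kind != "unmapped")
  # zero false negatives, zero false positives, exact counts
  expect_setequal(hits$seq, mapped_truth$seq)
  m <- mapped_truth |> dplyr::left_join(hits, by = "seq")
  expect_identical(m$category, m$kind)
  expect_identical(m$count.y, m$count.x)
  # unmapped total matches the junk + filtered plantings
  expect_identical(fx_profile$summary$unmapped_reads,
                   sum(truth$count[truth$kind == "unmapped"]))
})

test_that("an NTA hit's templated core is always a wild-type key", {
  nta <- fx_profile$hits |> dplyr::filter(category == "nta")
  expect_gt(nrow(nta), 0L)
  expect_true(all(nta$templated_core %in% fx_bundle$wildtype$seq))
  expect_identical(paste0(nta$templated_core, nta$tail), nta$seq)
})

test_that("profiling is invariant under read-order permutation", {
  d <- withr::local_tempdir()
  f2 <- file.path(d, "perm.fastq")
  simulate_reads(fx_recipe, f2, seed = 999L)
  p2 <- profile_reads(f2, fx_bundle)
  expect_identical(as.data.frame(p2$hits), as.data.frame(fx_profile$hits))
  expect_identical(as.data.frame(p2$summary),
                   as.data.frame(fx_profile$summary))
})

test_that("tidy and glance expose the hit table and run summary", {
  expect_identical(tidy(fx_profile), tibble::as_tibble(fx_profile$hits))
  expect_identical(glance(fx_profile), fx_profile$summary)
  expect_s3_class(autoplot(fx_profile), "ggplot")
  expect_s3_class(plot_length_distribution(fx_profile), "ggplot")
})
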