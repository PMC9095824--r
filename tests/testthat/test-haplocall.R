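test_that("Kulczynski scoring matches hand-enumerated cases", {
  tree <- fixture_tree()
  panel <- fixture_panel(tree)
  ref <- reference_alleles(tree)
  key <- as.character(panel$position)

  # perfect match against M39 (expected derived at 489, 10400, 12361)
  s1 <- sample_genotypes("s1", profile_calls(tree, panel, "M39"))
  sc1 <- score_haplogroup(s1, "M39", tree, panel)
  expect_equal(as.numeric(sc1), 1.0)
  expect_equal(attr(sc1, "n_expected"), 3L)
  expect_equal(attr(sc1, "n_matched"), 3L)

  # 1 of 2 evaluable expected derived states matched plus 1 extra derived
  # call: evaluate M39 on a sample with 489 derived, 12361 MISSING,
  # 10400 reference (miss), and a derived call at 12705.
  calls <- ref[key]
  calls["489"] <- "C"       # matches M39
  calls["12361"] <- NA      # MISSING, excluded
  calls["12705"] <- "C"     # extra derived (R variant)
  s2 <- sample_genotypes("s2", calls)
  sc2 <- score_haplogroup(s2, "M39", tree, panel)
  # evaluable expected derived: 489, 10400 -> matched 1/2;
  # observed derived: 489, 12705 -> matched 1/2
  expect_equal(as.numeric(sc2), 0.5)

  # all-reference sample against the root: both ratios 0/0 = 1
  s3 <- sample_genotypes("s3", ref[key])
  expect_equal(as.numeric(score_haplogroup(s3, "rCRS", tree, panel)), 1.0)

  # a sample with every call MISSING is an error, not a number
  s4 <- sample_genotypes("s4", stats::setNames(rep(NA_character_,
                                                   length(key)), key))
  expect_error(score_haplogroup(s4, "M39", tree, panel), "evaluable")
  expect_error(score_haplogroup(s1, "Z9", tree, panel), "unknown")
})

test_that("best-haplogroup calls recover generators and break ties by depth", {
  tree <- fixture_tree()
  panel <- fixture_panel(tree)
  ref <- reference_alleles(tree)
  key <- as.character(panel$position)

  # noise-free R32 genotypes -> R32 at score 1
  cl <- call_haplogroup(sample_genotypes("r", profile_calls(tree, panel,
                                                            "R32")),
                        tree, panel)
  expect_equal(cl$best, "R32")
  expect_equal(cl$score, 1.0)
  expect_true(all(cl$alternatives$score <= cl$score))

  # child's defining site MISSING: M39 genotypes with 12361 dropped tie M
  # and M39; the deeper node wins
  calls <- profile_calls(tree, panel, "M39")
  calls["12361"] <- NA
  cl2 <- call_haplogroup(sample_genotypes("m", calls), tree, panel)
  expect_equal(cl2$best, "M39")

  # the oracle agrees on the same degenerate fixture
  orc <- oracle_call(sample_genotypes("m", calls), tree, panel)
  expect_equal(orc$label, "M39")
})

test_that("caller equals the exhaustive brute-force oracle on noisy cohorts", {
  tree <- default_haplotree()
  panel <- default_panel()
  labs <- c("M39", "R32", "HV0e", "U2a", "M5", "D", "K", "rCRS")
  spec <- cohort_spec(24, stats::setNames(rep(1 / length(labs),
                                              length(labs)), labs),
                      missing_rate = 0.25, error_rate = 0.05, seed = 99)
  sim <- simulate_cohort_genotypes(spec, tree, panel)
  for (s in sim$samples) {
    got <- call_haplogroup(s, tree, panel)
    orc <- oracle_call(s, tree, panel)
    expect_equal(got$best, orc$label, info = s$sample_id)
    expect_equal(got$score, orc$score, tolerance = 1e-12)
  }
})

test_that("adding a matching expected derived call never lowers the score", {
  tree <- default_haplotree()
  panel <- default_panel()
  ref <- reference_alleles(tree)
  key <- as.character(panel$position)
  for (label in c("M39", "R32", "HV0e", "U2a")) {
    prof_calls <- profile_calls(tree, panel, label)
    derived_pos <- key[prof_calls != ref[key]]
    calls <- ref[key]
    calls[derived_pos] <- NA # start with all diagnostic sites missing
    prev <- as.numeric(score_haplogroup(sample_genotypes("x", calls),
                                        label, tree, panel))
    for (p in derived_pos) {
      calls[p] <- prof_calls[p]
      cur <- as.numeric(score_haplogroup(sample_genotypes("x", calls),
                                         label, tree, panel))
      expect_gte(cur, prev)
      prev <- cur
    }
    expect_equal(prev, 1.0)
  }
})

test_that("cohort calling tabulates haplogroup and macro frequencies", {
  tree <- default_haplotree()
  panel <- default_panel()
  # 50 samples: 12 M39, 7 R32, 3 HV0e, 28 others -> published-style table
  comp <- c(rep("M39", 12), rep("R32", 7), rep("HV0e", 3), rep("M2", 10),
            rep("M5", 8), rep("U2a", 5), rep("D", 5))
  samples <- lapply(seq_along(comp), function(i) {
    sample_genotypes(paste0("s", i), profile_calls(tree, panel, comp[i]))
  })
  cc <- call_cohort(samples, tree, panel)
  expect_equal(unname(cc$frequencies["M39"]), 0.24)
  expect_equal(unname(cc$frequencies["R32"]), 0.14)
  expect_equal(sum(cc$frequencies), 1.0)
  expect_equal(sum(cc$macro_frequencies), 1.0)
  # 12+7+3 is not all of M: M39, M2, M5, D descend from M; R32 from R
  expect_equal(unname(cc$macro_frequencies[["M"]]), 35 / 50)
  expect_equal(unname(cc$macro_frequencies[["R"]]), 15 / 50)

  single <- call_cohort(samples[1], tree, panel)
  expect_equal(unname(single$frequencies), 1.0)
  expect_error(call_cohort(list(), tree, panel), "empty")

  df <- as.data.frame(cc)
  expect_equal(nrow(df), 50L)
  expect_true(all(df$n_matched <= pmin(df$n_expected,
                                       df$n_observed_derived)))
})

test_that("long-format genotype CSV round-trips through the reader", {
  tree <- default_haplotree()
  panel <- default_panel()
  sim <- simulate_cohort_genotypes(
    cohort_spec(5, c(M39 = 0.5, R32 = 0.5), missing_rate = 0.2, seed = 4),
    tree, panel)
  f <- withr::local_tempfile(fileext = ".csv")
  long <- do.call(rbind, lapply(sim$samples, function(s) {
    data.frame(sample_id = s$sample_id, position = names(s$calls),
               allele = ifelse(is.na(s$calls), "N", s$calls))
  }))
  utils::write.csv(long, f, row.names = FALSE, quote = FALSE)
  back <- read_genotypes_csv(f, panel)
  expect_length(back, 5L)
  for (s in sim$samples) {
    expect_identical(back[[s$sample_id]]$calls[names(s$calls)], s$calls)
  }
})

test_that("VCF genotypes collapse to haploid calls, hets become MISSING", {
  tree <- default_haplotree()
  panel <- default_panel()
  pos <- panel$position[1:3]
  ref <- reference_alleles(tree)
  alt <- vapply(as.character(pos), function(p) {
    setdiff(c("A", "C", "G", "T"), ref[p])[1]
  }, "")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "sampleA", "sampleB", sep = "\t"),
    paste("chrM", pos[1], ".", ref[as.character(pos[1])], alt[1], ".",
          "PASS", ".", "GT", "1/1", "0/0", sep = "\t"),
    paste("chrM", pos[2], ".", ref[as.character(pos[2])], alt[2], ".",
          "PASS", ".", "GT", "0/1", "1/1", sep = "\t"),
    paste("chrM", pos[3], ".", ref[as.character(pos[3])], alt[3], ".",
          "PASS", ".", "GT", "./.", "0/0", sep = "\t")
  ), f)
  got <- read_genotypes_vcf(f, panel)
  names(got) <- vapply(got, `[[`, character(1), "sample_id")
  a <- got[["sampleA"]]$calls
  b <- got[["sampleB"]]$calls
  expect_equal(unname(a[as.character(pos[1])]), unname(alt[1])) # hom alt
  expect_true(is.na(a[as.character(pos[2])]))           # het -> MISSING
  expect_true(is.na(a[as.character(pos[3])]))           # no call
  expect_equal(unname(b[as.character(pos[1])]),
               unname(ref[as.character(pos[1])]))       # hom ref
  expect_equal(unname(b[as.character(pos[2])]), unname(alt[2]))
  # positions not in the VCF stay MISSING
  expect_true(all(is.na(a[as.character(panel$position[-(1:3)])])))
})
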