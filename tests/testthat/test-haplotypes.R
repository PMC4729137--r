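toy_variants <- function(ref, pos, alts) {
  data.frame(pos = pos,
             ref = vapply(pos, function(p) substr(ref, p, p), character(1)),
             alt = alts, stringsAsFactors = FALSE)
}

test_that("single-site pattern counting matches direct proportions", {
  ref <- random_reference(100, seed = 20)
  alt <- alt_base(ref, 50)
  mut <- ref; substr(mut, 50, 50) <- alt
  reads <- make_reads(c(rep(ref, 90), rep(mut, 10)), 1, ref)
  pat <- assign_read_patterns(reads, toy_variants(ref, 50, alt),
                              pipeline_config())
  expect_equal(nrow(pat), 1L)
  expect_equal(pat$mutant_reads, 10L)
  expect_equal(pat$total_reads, 100L)
})

test_that("two-site patterns are exclusive and share coverage totals", {
  ref <- random_reference(100, seed = 21)
  a1 <- alt_base(ref, 30); a2 <- alt_base(ref, 70)
  m1 <- ref; substr(m1, 30, 30) <- a1
  m2 <- ref; substr(m2, 70, 70) <- a2
  m12 <- m1; substr(m12, 70, 70) <- a2
  reads <- make_reads(c(rep(ref, 50), rep(m1, 30), rep(m2, 15), rep(m12, 5)),
                      1, ref)
  vars <- toy_variants(ref, c(30, 70), c(a1, a2))
  pat <- assign_read_patterns(reads, vars, pipeline_config())
  got <- stats::setNames(pat$mutant_reads, pat$label)
  lbl1 <- paste0("30", substr(ref, 30, 30), ">", a1)
  lbl2 <- paste0("70", substr(ref, 70, 70), ">", a2)
  expect_equal(got[[lbl1]], 30L)
  expect_equal(got[[lbl2]], 15L)
  expect_equal(got[[paste0(lbl1, "/", lbl2)]], 5L)
  expect_true(all(pat$total_reads == 100L))
})

test_that("high-mismatch reads are excluded only with multiple called sites", {
  ref <- random_reference(100, seed = 22)
  a1 <- alt_base(ref, 30); a2 <- alt_base(ref, 70)
  noisy <- ref
  for (p in c(30, 70, 1:6)) {  # 8 mismatches total
    substr(noisy, p, p) <- alt_base(ref, p)
  }
  clean12 <- ref
  substr(clean12, 30, 30) <- a1; substr(clean12, 70, 70) <- a2
  reads <- make_reads(c(rep(ref, 10), clean12, noisy), 1, ref)
  expect_equal(reads$nm[12], 8L)

  vars2 <- toy_variants(ref, c(30, 70), c(a1, a2))
  pat <- assign_read_patterns(reads, vars2, pipeline_config())
  expect_equal(attr(pat, "n_informative"), 11L)  # noisy read dropped
  expect_equal(sum(pat$mutant_reads), 1L)        # only the clean double

  # with a single called site the cap does not apply
  vars1 <- toy_variants(ref, 30, a1)
  pat1 <- assign_read_patterns(reads, vars1, pipeline_config())
  expect_equal(attr(pat1, "n_informative"), 12L)
  expect_equal(pat1$mutant_reads, 2L)            # clean12 and noisy both carry alt
})

test_that("low-quality bases make a read uninformative at that site", {
  ref <- random_reference(100, seed = 23)
  alt <- alt_base(ref, 40)
  mut <- ref; substr(mut, 40, 40) <- alt
  quals <- c(lapply(1:5, function(i) rep(40L, 100)),
             list(c(rep(40L, 39), 20L, rep(40L, 60))))  # low qual at site
  reads <- make_reads(c(rep(ref, 4), mut, mut), 1, ref, quals = quals)
  pat <- assign_read_patterns(reads, toy_variants(ref, 40, alt),
                              pipeline_config())
  expect_equal(pat$total_reads, 5L)   # the low-qual read observes nothing there
  expect_equal(pat$mutant_reads, 1L)
})

test_that("haplotype rows satisfy the count arithmetic and ordering", {
  ref <- random_reference(100, seed = 24)
  a1 <- alt_base(ref, 20); a2 <- alt_base(ref, 80)
  m1 <- ref; substr(m1, 20, 20) <- a1
  m2 <- ref; substr(m2, 80, 80) <- a2
  reads <- make_reads(c(rep(ref, 70), rep(m1, 25), rep(m2, 5)), 1, ref)
  vars <- toy_variants(ref, c(20, 80), c(a1, a2))
  ht <- build_haplotype_table(assign_read_patterns(reads, vars,
                                                   pipeline_config()))
  expect_equal(ht$mutant_reads + ht$wildtype_reads, ht$total_reads)
  expect_equal(ht$percent, percent_mutant(ht$mutant_reads, ht$total_reads))
  expect_true(all(diff(ht$mutant_reads) <= 0))  # descending
})

test_that("watch-listed patterns appear with zero support; others do not", {
  ref <- random_reference(100, seed = 25)
  a1 <- alt_base(ref, 20); a2 <- alt_base(ref, 80)
  m1 <- ref; substr(m1, 20, 20) <- a1
  reads <- make_reads(c(rep(ref, 20), rep(m1, 5)), 1, ref)
  vars <- toy_variants(ref, c(20, 80), c(a1, a2))
  lbl2 <- paste0("80", substr(ref, 80, 80), ">", a2)
  pat <- assign_read_patterns(reads, vars, pipeline_config(),
                              watch = list(lbl2))
  ht <- build_haplotype_table(pat)
  expect_true(lbl2 %in% ht$label)
  row2 <- ht[ht$label == lbl2, ]
  expect_equal(row2$mutant_reads, 0L)
  expect_equal(row2$total_reads, 25L)
  expect_equal(row2$percent, 0)
  # no spurious double row: never observed and not watched
  expect_false(any(grepl("/", ht$label)))

  expect_equal(nrow(assign_read_patterns(reads, vars[0, ],
                                         pipeline_config())), 0L)
})

test_that("pattern counts partition the informative reads on full-length data", {
  ref <- random_reference(120, seed = 26)
  cfg <- pipeline_config()
  for (seed in 1:5) {
    spec <- sim_spec(ref,
                     list(list(subs = sub_at(40, alt_base(ref, 40)), freq = 0.12),
                          list(subs = c(sub_at(40, alt_base(ref, 40)),
                                        sub_at(90, alt_base(ref, 90))),
                               freq = 0.05)),
                     n_reads = 1500, base_error_rate = 0,
                     background = list(mean = 0, shape = 2), seed = seed)
    sim <- simulate_amplicon(spec)
    vars <- toy_variants(ref, c(40, 90),
                         c(alt_base(ref, 40), alt_base(ref, 90)))
    pat <- assign_read_patterns(sim$reads, vars, cfg)
    # zero noise, full length: every informative read is WT or one pattern
    wt <- attr(pat, "n_informative") - sum(pat$mutant_reads)
    expect_equal(sum(pat$mutant_reads) + wt, nrow(sim$reads))
    # realized haplotype counts are recovered exactly
    expect_setequal(pat$mutant_reads,
                    unname(sim$truth$realized_counts[-1]))
  }
})

test_that("estimated haplotype frequencies track simulated mixtures", {
  ref <- random_reference(120, seed = 27)
  cfg <- pipeline_config(regime = "wga2")
  ok <- 0L
  n_checks <- 0L
  for (seed in 1:10) {
    f1 <- 0.08; f2 <- 0.03
    spec <- sim_spec(ref,
                     list(list(subs = sub_at(40, alt_base(ref, 40)), freq = f1),
                          list(subs = sub_at(90, alt_base(ref, 90)), freq = f2)),
                     n_reads = 4000, regime = "wga2", seed = seed)
    sim <- simulate_amplicon(spec)
    vars <- toy_variants(ref, c(40, 90),
                         c(alt_base(ref, 40), alt_base(ref, 90)))
    ht <- build_haplotype_table(assign_read_patterns(sim$reads, vars, cfg))
    for (j in seq_len(nrow(ht))) {
      f <- if (grepl("^40", ht$label[j])) f1 else f2
      se <- sqrt(f * (1 - f) / ht$total_reads[j])
      n_checks <- n_checks + 1L
      if (abs(ht$percent[j] / 100 - f) <= 3 * se) ok <- ok + 1L
    }
  }
  expect_gte(ok / n_checks, 0.95)
})
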