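test_that("background estimation pools below-floor observations with population sd", {
  # 12 positions, depth 1000: one alt at 0.1%, one at 0.2%, all else 0
  counts <- matrix(0L, nrow = 12, ncol = 4)
  ref <- paste(rep("A", 12), collapse = "")
  counts[, 1] <- 1000L
  counts[1, 3] <- 1L; counts[1, 1] <- 999L   # 0.1% G at pos 1
  counts[2, 4] <- 2L; counts[2, 1] <- 998L   # 0.2% T at pos 2

  # native floor 0.1: both non-zero observations are at/above the floor and
  # excluded; the remaining zeros estimate a zero background
  native <- make_count_table(counts, ref, pipeline_config())
  bg <- estimate_background(native)
  expect_equal(bg$mean, 0)
  expect_equal(bg$sd, 0)
  expect_equal(bg$n_observations, 34L)

  # wga2 floor 1.0 excludes nothing; frozen hand arithmetic on the multiset
  wcfg <- pipeline_config(regime = "wga2")
  wga2 <- make_count_table(counts, ref, wcfg)
  bgw <- estimate_background(wga2)
  v <- c(0.1, 0.2, rep(0, 34))
  expect_equal(bgw$mean, mean(v))
  expect_equal(bgw$sd, sqrt(mean((v - mean(v))^2)))
})

test_that("background estimation signals degenerate inputs", {
  counts <- matrix(0L, nrow = 12, ncol = 4)
  counts[, 2] <- 100L
  ref <- paste(rep("C", 12), collapse = "")
  short <- make_count_table(counts[1:5, ], substr(ref, 1, 5))
  expect_error(estimate_background(short), "10")

  # every observation at or above the floor -> too few usable
  all_high <- matrix(0L, nrow = 12, ncol = 4)
  all_high[, 2] <- 90L
  all_high[, c(1, 3, 4)] <- 4L  # 4/102 = 3.9% each, above the native floor
  tab <- make_count_table(all_high, ref)
  expect_error(estimate_background(tab), "usable")
})

test_that("candidates require both the outlier rule and the regime floor", {
  fake_bg <- function(mean, sd)
    structure(list(mean = mean, sd = sd, n_observations = 100L, note = ""),
              class = "background_model")
  counts <- matrix(0L, nrow = 12, ncol = 4)
  ref <- paste(rep("A", 12), collapse = "")
  counts[, 1] <- 10000L
  counts[1, 3] <- 150L   # 1.5% (of 10150) -> ~1.48%
  counts[2, 4] <- 81L    # ~0.8%
  counts[3, 2] <- 15L    # ~0.15%
  wcfg <- pipeline_config(regime = "wga2")
  tab <- make_count_table(counts, ref, wcfg)
  cand <- call_candidates(tab, fake_bg(0.2, 0.1), wcfg)
  key <- paste(cand$pos, cand$alt)
  expect_true(cand$called[key == "1 G"])    # 1.48 > 0.6 and > 1.0
  g <- cand[key == "2 T", ]
  expect_true(g$passed_outlier)             # 0.8 > 0.6
  expect_false(g$passed_floor)              # but below the 1% wga2 floor
  expect_false(g$called)

  ncfg <- pipeline_config()
  ntab <- make_count_table(counts, ref, ncfg)
  ncand <- call_candidates(ntab, fake_bg(0.01, 0.02), ncfg)
  nkey <- paste(ncand$pos, ncand$alt)
  expect_true(ncand$called[nkey == "3 C"])  # 0.15 > 0.09 and > 0.1
})

test_that("ties at exactly the threshold fail (strict inequalities)", {
  fake_bg <- structure(list(mean = 0, sd = 0.05, n_observations = 100L,
                            note = ""), class = "background_model")
  counts <- matrix(0L, nrow = 12, ncol = 4)
  ref <- paste(rep("A", 12), collapse = "")
  counts[, 1] <- 9999L
  counts[1, 3] <- 20L  # exactly 0.2% of 10019? no: use depth to make 0.2 exact
  counts[1, 1] <- 9980L  # depth 10000, G = 20 -> exactly 0.20%
  cfg <- pipeline_config()
  tab <- make_count_table(counts, ref, cfg)
  cand <- call_candidates(tab, fake_bg, cfg)
  g <- cand[paste(cand$pos, cand$alt) == "1 G", ]
  expect_equal(g$percent, 0.2)
  expect_false(g$passed_outlier)  # 0.2 is not > 0 + 4*0.05
})

test_that("cohort artifact filter uses a strict more-than fraction", {
  cfg <- pipeline_config()
  fake_sample <- function(called) {
    counts <- matrix(0L, nrow = 12, ncol = 4)
    counts[, 1] <- 1000L
    if (called) { counts[5, 3] <- 30L; counts[5, 1] <- 970L }
    tab <- make_count_table(counts, paste(rep("A", 12), collapse = ""), cfg)
    bg <- structure(list(mean = 0, sd = 0.01, n_observations = 30L, note = ""),
                    class = "background_model")
    call_candidates(tab, bg, cfg)
  }
  mk <- function(n_called, n_total) {
    x <- lapply(seq_len(n_total), function(i) fake_sample(i <= n_called))
    stats::setNames(x, paste0("s", seq_len(n_total)))
  }

  eight <- filter_cohort_artifacts(mk(8, 10), cfg)
  flags <- vapply(eight, function(x)
    any(x$cohort_artifact[paste(x$pos, x$alt) == "5 G"]), logical(1))
  expect_true(all(flags))                                   # 0.8 > 0.75
  expect_false(any(vapply(eight, function(x) any(x$called), logical(1))))

  seven <- filter_cohort_artifacts(mk(7, 10), cfg)
  expect_false(any(vapply(seven, function(x) any(x$cohort_artifact),
                          logical(1))))                     # 0.7 <= 0.75

  three <- filter_cohort_artifacts(mk(3, 4), cfg)
  expect_false(any(vapply(three, function(x) any(x$cohort_artifact),
                          logical(1))))                     # exactly 75% kept

  expect_warning(filter_cohort_artifacts(mk(1, 1), cfg), "fewer than 2")
})

test_that("patient-linked rescue needs a matched passing call and 2 sd", {
  cfg <- pipeline_config()
  sample_with <- function(pct_g5) {
    counts <- matrix(0L, nrow = 12, ncol = 4)
    counts[, 1] <- 10000L
    g <- round(pct_g5 * 100)  # depth 10000: count = pct * 100
    counts[5, 3] <- g; counts[5, 1] <- 10000L - g
    tab <- make_count_table(counts, paste(rep("A", 12), collapse = ""), cfg)
    bg <- structure(list(mean = 0.01, sd = 0.02, n_observations = 30L,
                         note = ""), class = "background_model")
    call_candidates(tab, bg, cfg)
  }
  grouping <- c(t1 = "P1", t2 = "P1", o1 = "P2")

  # t2 passes (0.5% > floor and outlier); t1 at mean + 3 sd (0.07%) but
  # below the 0.1% floor -> rescued
  calls <- list(t1 = sample_with(0.07), t2 = sample_with(0.5),
                o1 = sample_with(0))
  out <- rescue_patient_linked(calls, grouping, cfg)
  t1 <- out$t1[paste(out$t1$pos, out$t1$alt) == "5 G", ]
  expect_true(t1$rescued)
  expect_true(t1$called)
  expect_false(t1$passed_floor)

  # at mean + 1 sd (0.03%) -> not rescued
  calls2 <- list(t1 = sample_with(0.03), t2 = sample_with(0.5),
                 o1 = sample_with(0))
  out2 <- rescue_patient_linked(calls2, grouping, cfg)
  expect_false(any(out2$t1$rescued))

  # passing call only in a different patient -> not rescued
  calls3 <- list(t1 = sample_with(0.07), t2 = sample_with(0),
                 o1 = sample_with(0.5))
  out3 <- rescue_patient_linked(calls3, grouping, cfg)
  expect_false(any(out3$t1$rescued))
})

test_that("the verdict invariant holds after every filtering stage", {
  cfg <- pipeline_config(regime = "wga2")
  ref <- random_reference(120, seed = 30)
  sims <- lapply(1:4, function(s) {
    spec <- sim_spec(ref, list(list(subs = sub_at(60, alt_base(ref, 60)),
                                    freq = 0.05)),
                     n_reads = 2000, regime = "wga2", seed = s)
    sim <- simulate_amplicon(spec)
    tab <- build_pileup(sim$reads, ref, cfg)
    call_candidates(tab, estimate_background(tab, cfg), cfg)
  })
  names(sims) <- paste0("s", 1:4)
  sims <- filter_cohort_artifacts(sims, cfg)
  sims <- rescue_patient_linked(sims, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"),
                                cfg)
  for (x in sims)
    expect_equal(x$called,
                 (x$passed_outlier & x$passed_floor & !x$cohort_artifact) |
                   x$rescued)
})

test_that("calls match the brute-force oracle on random small pileups", {
  cfg <- pipeline_config()
  set.seed(99)
  for (rep in 1:20) {
    L <- sample(10:20, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    counts <- matrix(0L, nrow = L, ncol = 4)
    refcode <- match(strsplit(ref, "")[[1]], c("A", "C", "G", "T"))
    for (i in seq_len(L)) {
      counts[i, refcode[i]] <- 900L + sample(0:200, 1)
      nerr <- sample(0:3, 1)
      if (nerr > 0) {
        alts <- setdiff(1:4, refcode[i])
        picked <- alts[sample.int(3, nerr)]
        counts[i, picked] <- sample(c(0:3, 15), nerr, replace = TRUE)
      }
    }
    tab <- make_count_table(counts, ref, cfg)
    bg <- tryCatch(estimate_background(tab), error = function(e) NULL)
    if (is.null(bg)) next
    cand <- call_candidates(tab, bg, cfg)
    ours <- sort(paste(cand$pos, cand$alt)[cand$called])
    expect_identical(ours, oracle_calls(tab, cfg))
  }
})
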