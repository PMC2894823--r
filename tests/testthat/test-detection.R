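# Sweep-line sub-CNVR detection: worked examples, boundary behaviour,
# oracle equivalence and the monotonicity/determinism properties.

test_that("minimum-SNP filter discards calls below the threshold, strictly", {
  calls <- make_calls(c("A", "B", "C"), "1", c(100, 200, 300),
                      c(900, 900, 900), n_snps = c(1L, 3L, 5L))
  kept <- filter_min_snps(calls, 3)
  expect_equal(kept$n_snps, c(3L, 5L))
  expect_equal(filter_min_snps(calls, 1), calls)    # identity
  expect_equal(nrow(filter_min_snps(calls[0, ], 3)), 0L)
  expect_error(filter_min_snps(calls, 0), "min_snps")
})

test_that("coverage profile enumerates per-segment carrier counts", {
  expect_equal(nrow(coverage_profile(make_calls("A", "1", 1, 1)[0, ], "1")),
               0L)
  one <- coverage_profile(make_calls("A", "1", 100, 500), "1")
  expect_equal(one$count, 1L)
  expect_equal(c(one$start, one$end), c(100, 500))

  three <- coverage_profile(
    make_calls(c("A", "B", "C"), "1", c(100, 200, 200), c(300, 400, 300)),
    "1")
  expect_equal(three$count, c(1L, 3L, 1L))
  # sum(count * length) equals the total deduplicated covered length
  expect_equal(sum(three$count * three$length),
               (300 - 100) + (400 - 200) + (300 - 200))
})

test_that("sub-CNVR detection matches the worked three-subject example", {
  calls <- make_calls(c("A", "B", "C"), "1", c(100, 200, 200),
                      c(300, 400, 300))
  sub <- detect_sub_cnvrs(calls, 4, detection_config(0.5))
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$start, 200)
  expect_equal(sub$end, 300)
  expect_equal(sub$frequency, 0.75)
  expect_equal(sub$carriers[[1]], c("A", "B", "C"))
  # strict inequality at the boundary: 0.75 is not > 0.75
  expect_equal(nrow(detect_sub_cnvrs(calls, 4, detection_config(0.75))), 0L)
})

test_that("single subject, single CNV is its own region at full frequency", {
  sub <- detect_sub_cnvrs(make_calls("A", "1", 100, 500), 1,
                          detection_config(0.5))
  expect_equal(nrow(sub), 1L)
  expect_equal(c(sub$start, sub$end), c(100, 500))
  expect_equal(sub$frequency, 1.0)
  expect_equal(nrow(detect_sub_cnvrs(make_calls("A", "1", 1, 1)[0, ], 5,
                                     detection_config(0.1))), 0L)
})

test_that("a subject's overlapping calls count once (subjects, not calls)", {
  # two overlapping calls of one subject + one call of another
  calls <- make_calls(c("A", "A", "B"), "1", c(100, 250, 100),
                      c(300, 500, 500))
  sub <- detect_sub_cnvrs(calls, 2, detection_config(0.6))
  # subject A covers [100,500) via two calls; both segments carry 2 subjects
  expect_true(all(sub$n_carriers == 2L))
  expect_equal(min(sub$start), 100)
  expect_equal(max(sub$end), 500)
})

test_that("chromosomes never combine and calls off the SNP map error", {
  calls <- make_calls(c("A", "B"), c("1", "2"), 100, 300)
  sub <- detect_sub_cnvrs(calls, 2, detection_config(0.25))
  expect_equal(sort(unique(sub$chromosome)), c("1", "2"))
  snp_map <- data.frame(marker_id = "rs1", chromosome = "1", position = 50)
  expect_error(detect_sub_cnvrs(calls, 2, detection_config(0.25),
                                snp_map = snp_map),
               "absent from the SNP map")
  expect_error(detect_sub_cnvrs(calls, 0, detection_config(0.25)),
               "n_subjects")
})

test_that("detection agrees with the brute-force coverage oracle on random cohorts", {
  set.seed(42)
  thresholds <- seq(0.05, 0.5, by = 0.05)
  for (rep in 1:150) {
    inst <- random_instance()
    thr <- sample(thresholds, 1)
    expect_detect_matches_oracle(inst$calls, inst$n_subjects, thr)
  }
})

test_that("raising the frequency threshold never adds regions or covered length", {
  set.seed(7)
  for (rep in 1:40) {
    inst <- random_instance()
    prev_n <- Inf; prev_len <- Inf
    for (thr in c(0.05, 0.10, 0.15, 0.20, 0.25)) {
      sub <- detect_sub_cnvrs(inst$calls, inst$n_subjects,
                              detection_config(thr))
      covered <- if (nrow(sub)) sum(sub$end - sub$start) else 0
      expect_lte(nrow(sub), prev_n)
      expect_lte(covered, prev_len)
      prev_n <- nrow(sub); prev_len <- covered
    }
  }
})

test_that("detection is deterministic and invariant to input row order", {
  set.seed(99)
  inst <- random_instance()
  sub1 <- detect_sub_cnvrs(inst$calls, inst$n_subjects,
                           detection_config(0.15))
  shuffled <- inst$calls[sample(nrow(inst$calls)), ]
  sub2 <- detect_sub_cnvrs(shuffled, inst$n_subjects, detection_config(0.15))
  expect_equal(as.data.frame(sub1), as.data.frame(sub2))
})

test_that("reported frequencies are exact carrier ratios", {
  set.seed(11)
  inst <- random_instance()
  sub <- detect_sub_cnvrs(inst$calls, inst$n_subjects, detection_config(0.1))
  if (nrow(sub)) {
    expect_identical(sub$frequency, sub$n_carriers / inst$n_subjects)
    expect_equal(sub$n_carriers, lengths(sub$carriers))
    expect_true(all(sub$frequency > 0.1))
  }
})

test_that("separate loss/gain detection splits pooled regions by direction", {
  calls <- make_calls(c("A", "B", "C", "D"), "1", 100, 500,
                      dose = c(-1, -1, 1, 1))
  pooled <- detect_sub_cnvrs(calls, 4, detection_config(0.5))
  expect_equal(pooled$frequency, 1.0)
  separate <- detect_sub_cnvrs(calls, 4,
                               detection_config(0.25, pool_states = FALSE))
  expect_equal(nrow(separate), 2L)
  expect_setequal(separate$state_class, c("loss", "gain"))
  expect_equal(separate$frequency, c(0.5, 0.5))
})
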