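# Extended algorithm: merging consecutive sub-CNVRs and assigning states.

sub_fixture <- function() {
  # segments [200,300) and [300,450) each carried by 2 of 4 subjects:
  # both above threshold 0.4 and sharing the event position 300
  calls <- make_calls(c("A", "B", "C"), "1", c(200, 200, 300),
                      c(450, 300, 450))
  detect_sub_cnvrs(calls, 4, detection_config(0.4))
}

test_that("boundary-sharing sub-CNVRs merge into one region", {
  sub <- sub_fixture()
  expect_equal(nrow(sub), 2L)
  expect_equal(sub$start, c(200, 300))
  expect_equal(sub$end, c(300, 450))
  merged <- merge_sub_cnvrs(sub)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(200, 450))
  expect_equal(merged$n_members, 2L)
  expect_equal(merged$region_length, 251)
  # frequency recomputed over the merged span: carriers anywhere inside
  expect_equal(merged$carriers[[1]], c("A", "B", "C"))
  expect_equal(merged$frequency, 0.75)
})

test_that("a single sub-CNVR merges to an identical region", {
  calls <- make_calls("A", "1", 100, 500)
  sub <- detect_sub_cnvrs(calls, 1, detection_config(0.5))
  merged <- merge_sub_cnvrs(sub)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(sub$start, sub$end))
  expect_equal(merged$n_members, 1L)
})

test_that("regions on different chromosomes never merge", {
  calls <- make_calls(c("A", "A"), c("1", "2"), 200, 300)
  sub <- detect_sub_cnvrs(calls, 1, detection_config(0.5))
  merged <- merge_sub_cnvrs(sub)
  expect_equal(nrow(merged), 2L)
  expect_setequal(merged$chromosome, c("1", "2"))
})

test_that("non-adjacent regions (below-threshold gap) stay separate", {
  # gap [300,400) carried only by A: below the 0.5 threshold at n=2
  calls <- make_calls(c("A", "B", "B"), "1", c(100, 100, 400),
                      c(500, 300, 500))
  sub <- detect_sub_cnvrs(calls, 2, detection_config(0.5))
  expect_equal(nrow(sub), 2L)
  merged <- merge_sub_cnvrs(sub)
  expect_equal(nrow(merged), 2L)
})

test_that("splitting at member boundaries recovers the basic output exactly", {
  set.seed(5)
  for (rep in 1:25) {
    inst <- random_instance()
    sub <- detect_sub_cnvrs(inst$calls, inst$n_subjects,
                            detection_config(0.1))
    merged <- merge_sub_cnvrs(sub)
    expect_lte(nrow(merged), nrow(sub))
    back <- split_cnvrs(merged)
    expect_equal(as.data.frame(back), as.data.frame(sub),
                 ignore_attr = TRUE)
    if (nrow(merged)) {
      # merged spans cover all member spans
      expect_equal(sum(merged$n_members), nrow(sub))
      expect_true(all(merged$end - merged$start + 1 == merged$region_length))
    }
  }
})

test_that("unsorted input to merge is a contract violation", {
  sub <- sub_fixture()
  expect_error(merge_sub_cnvrs(sub[rev(seq_len(nrow(sub))), ]), "sorted")
})

test_that("state assignment follows the strict longest-overlap rule", {
  region <- data.frame(region_id = "1:200-400", chromosome = "1",
                       start = 200, end = 400, region_length = 201)
  cfg <- detection_config(0.5, state_len_threshold = 0.5)
  # loss overlapping 150 bp of a 201-bp region: 150/201 > 0.5 => state -1
  calls <- make_calls("A", "1", 251, 450, dose = -1)
  st <- assign_states(region, calls, cfg, subjects = c("A", "B"))
  expect_equal(unname(st["1:200-400", ]), c(-1, 0))

  # overlap fraction exactly at the threshold: strict '>' gives state 0
  region2 <- data.frame(region_id = "1:1-200", chromosome = "1",
                        start = 1, end = 200, region_length = 200)
  exact <- make_calls("A", "1", 101, 200, dose = 1)   # overlap 100 = half
  st2 <- assign_states(region2, exact, cfg, subjects = "A")
  expect_equal(unname(st2[1, 1]), 0)
  above <- make_calls("A", "1", 100, 200, dose = 1)   # overlap 101 > half
  st3 <- assign_states(region2, above, cfg, subjects = "A")
  expect_equal(unname(st3[1, 1]), 1)
})

test_that("the longest overlapping CNV wins; ties break deterministically", {
  region <- data.frame(region_id = "1:100-500", chromosome = "1",
                       start = 100, end = 500, region_length = 401)
  cfg <- detection_config(0.5)
  # same subject: gain overlaps 301 bp, loss only 150 => gain wins
  calls <- rbind(make_calls("A", "1", 100, 400, dose = 1),
                 make_calls("A", "1", 351, 500, dose = -1))
  st <- assign_states(region, calls, cfg, subjects = "A")
  expect_equal(unname(st[1, 1]), 1)
  # equal overlap, different |dose|: larger magnitude wins
  tie <- rbind(make_calls("B", "1", 100, 300, dose = -2),
               make_calls("B", "1", 300, 500, dose = 1))
  st2 <- assign_states(region, tie, cfg, subjects = "B")
  expect_equal(unname(st2[1, 1]), -2)
})

test_that("absolute-bp state rule is available as an alternative", {
  region <- data.frame(region_id = "1:100-500", chromosome = "1",
                       start = 100, end = 500, region_length = 401)
  calls <- make_calls("A", "1", 100, 260, dose = -1)  # overlap 161 bp
  cfg_bp <- detection_config(0.5, state_len_bp = 150)
  expect_equal(unname(assign_states(region, calls, cfg_bp,
                                    subjects = "A")[1, 1]), -1)
  cfg_bp2 <- detection_config(0.5, state_len_bp = 200)
  expect_equal(unname(assign_states(region, calls, cfg_bp2,
                                    subjects = "A")[1, 1]), 0)
})

test_that("subjects with no overlapping CNV get state 0 and zero-length regions error", {
  region <- data.frame(region_id = "r", chromosome = "1", start = 100,
                       end = 400, region_length = 301)
  st <- assign_states(region, make_calls("A", "2", 100, 400),
                      detection_config(0.5), subjects = c("A", "B"))
  expect_true(all(st == 0))
  bad <- data.frame(region_id = "r", chromosome = "1", start = 100,
                    end = 400, region_length = 0)
  expect_error(assign_states(bad, make_calls("A", "1", 100, 400),
                             detection_config(0.5), subjects = "A"),
               "length")
})
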