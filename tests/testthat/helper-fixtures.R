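# Shared fixture builders and the brute-force detection oracle.

make_calls <- function(subject_id, chromosome = "1", start, end,
                       dose = -1, n_snps = 10L) {
  n <- max(length(subject_id), length(start), length(end))
  data.frame(
    subject_id = rep_len(subject_id, n),
    chromosome = rep_len(as.character(chromosome), n),
    start = rep_len(start, n), end = rep_len(end, n),
    state = as.character(dose_to_cn(rep_len(dose, n))),
    dose = rep_len(dose, n),
    n_snps = rep_len(as.integer(n_snps), n),
    start_marker = NA_character_, end_marker = NA_character_,
    stringsAsFactors = FALSE)
}

# Brute-force sub-CNVR detector built on coverage_profile: every
# inter-event segment above the threshold is a region; carriers are the
# distinct subjects with a call fully covering the segment (no sweep, no
# per-subject interval merging - a segment contains no event strictly
# inside it, so union coverage implies single-call coverage).
oracle_detect <- function(calls, n_subjects, thr) {
  out <- list()
  for (chrom in chrom_levels(calls$chromosome)) {
    prof <- coverage_profile(calls, chrom)
    cc <- calls[calls$chromosome == chrom, , drop = FALSE]
    above <- which(prof$count / n_subjects > thr)
    for (k in above) {
      carriers <- sort(unique(cc$subject_id[
        cc$start <= prof$start[k] & cc$end >= prof$end[k]]))
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom, start = prof$start[k], end = prof$end[k],
        n_carriers = length(carriers),
        frequency = length(carriers) / n_subjects,
        carriers = I(list(carriers)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_carriers = integer(),
                      frequency = numeric(), carriers = I(list())))
  }
  do.call(rbind, out)
}

# Random small cohort: <= 20 subjects, <= 60 distinct SNP positions over
# 1-2 chromosomes, <= 6 CNVs per subject.
random_instance <- function() {
  n_subjects <- sample(2:20, 1)
  n_chrom <- sample(1:2, 1)
  calls <- list()
  for (chrom in as.character(seq_len(n_chrom))) {
    grid <- sort(sample.int(6000, sample(8:60, 1))) * 100
    for (s in seq_len(n_subjects)) {
      n_cnv <- sample(0:6, 1)
      for (i in seq_len(n_cnv)) {
        idx <- sort(sample.int(length(grid), 2))
        calls[[length(calls) + 1L]] <- make_calls(
          sprintf("S%02d", s), chrom, grid[idx[1]], grid[idx[2]],
          dose = sample(c(-2, -1, 1, 2), 1))
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else make_calls(
    "S01", "1", 100, 200)
  list(calls = calls, n_subjects = n_subjects)
}

expect_detect_matches_oracle <- function(calls, n_subjects, thr) {
  got <- detect_sub_cnvrs(calls, n_subjects, detection_config(thr))
  want <- oracle_detect(calls, n_subjects, thr)
  got <- as.data.frame(got)
  expect_equal(nrow(got), nrow(want))
  if (nrow(want)) {
    o1 <- order(factor(got$chromosome,
                       levels = chrom_levels(got$chromosome)), got$start)
    o2 <- order(factor(want$chromosome,
                       levels = chrom_levels(want$chromosome)), want$start)
    expect_equal(got$start[o1], want$start[o2])
    expect_equal(got$end[o1], want$end[o2])
    expect_equal(got$n_carriers[o1], want$n_carriers[o2])
    expect_equal(got$frequency[o1], want$frequency[o2])
    expect_equal(got$carriers[o1], want$carriers[o2],
                 ignore_attr = TRUE)
  }
  invisible(got)
}

# Simulated null region/state set for association calibration runs: m
# independent regions, each with ~freq carriers of a +/-1 dose state.
simulate_null_states <- function(n_subjects, m, freq = 0.2) {
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  states <- matrix(0, m, n_subjects,
                   dimnames = list(sprintf("r%03d", seq_len(m)), subjects))
  for (i in seq_len(m)) {
    carriers <- runif(n_subjects) < freq
    states[i, carriers] <- sample(c(-1, 1), sum(carriers), replace = TRUE)
  }
  regions <- data.frame(
    region_id = rownames(states), chromosome = "1",
    start = seq_len(m) * 1000, end = seq_len(m) * 1000 + 500,
    region_length = 501, frequency = rowMeans(states != 0),
    n_carriers = rowSums(states != 0), stringsAsFactors = FALSE)
  list(regions = regions, states = states, subjects = subjects)
}
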