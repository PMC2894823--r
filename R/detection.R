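# Sub-CNVR detection.
#
# A CNV region (CNVR) is the union of overlapping CNVs across subjects;
# because whole CNVRs are too long to test as a unit, they are subdivided
# into sub-CNVRs at every change in carrier count. The basic detector
# reports every inter-event segment whose carrier frequency strictly
# exceeds the threshold; the extended algorithm (merge_sub_cnvrs) fuses
# consecutive above-threshold segments into longer regions and a second
# threshold then defines each subject's state in the merged region.
#
# Coordinate conventions: calls are 1-based closed [start, end]; for
# counting, a call covers the inter-event segments half-open [start, end)
# (the counter increments at the starting SNP and decrements at the ending
# SNP, and all events at one physical position are applied before any
# segment is evaluated). A reported sub-CNVR [a, b] is therefore bracketed
# by the event positions a (opening) and b (closing); a 1-bp call covers no
# segment.

#' Detection parameters
#'
#' @param freq_threshold fraction in (0,1): a segment is reported only if
#'   its carrier frequency is strictly greater than this threshold.
#' @param min_snps minimum number of consecutive array SNPs a call must
#'   span; calls supported by fewer SNPs are discarded before detection.
#' @param merge logical: run the extended algorithm
#'   ([merge_sub_cnvrs()]) after basic detection.
#' @param state_len_threshold fraction in (0,1]: a subject's longest CNV in
#'   a region defines their state only if its overlap exceeds this fraction
#'   of the region length (strict inequality); otherwise the state is 0.
#' @param pool_states logical: count gains and losses together (the
#'   default); if `FALSE`, losses and gains are detected as separate region
#'   sets.
#' @param state_len_bp optional absolute alternative to
#'   `state_len_threshold`: qualify a state when the overlap exceeds this
#'   many bp instead of a fraction of the region length.
#' @return a `detection_config` list.
#' @export
detection_config <- function(freq_threshold = 0.05, min_snps = 1,
                             merge = FALSE, state_len_threshold = 0.5,
                             pool_states = TRUE, state_len_bp = NULL) {
  if (!is.numeric(freq_threshold) || freq_threshold <= 0 ||
      freq_threshold >= 1) {
    cnv_stop("freq_threshold must be in (0,1)")
  }
  if (!is.numeric(min_snps) || min_snps < 1) {
    cnv_stop("min_snps must be an integer >= 1")
  }
  if (!is.numeric(state_len_threshold) || state_len_threshold <= 0 ||
      state_len_threshold > 1) {
    cnv_stop("state_len_threshold must be in (0,1]")
  }
  structure(list(freq_threshold = freq_threshold,
                 min_snps = as.integer(min_snps),
                 merge = isTRUE(merge),
                 state_len_threshold = state_len_threshold,
                 pool_states = isTRUE(pool_states),
                 state_len_bp = state_len_bp),
            class = "detection_config")
}

#' Discard calls supported by too few SNPs
#'
#' Calls that involve fewer SNPs than `min_snps` (strict "less than") are
#' discarded; order is preserved. Calls whose SNP count is missing are kept
#' with a warning: metadata gaps fail open, coordinate problems fail closed.
#'
#' @param calls a `cnv_calls` data frame.
#' @param min_snps integer >= 1.
#' @return the retained calls.
#' @export
filter_min_snps <- function(calls, min_snps) {
  if (!is.numeric(min_snps) || length(min_snps) != 1L || min_snps < 1) {
    cnv_stop("min_snps must be a single integer >= 1")
  }
  if (nrow(calls) == 0L) return(calls)
  missing <- is.na(calls$n_snps)
  if (any(missing) && min_snps > 1) {
    warning(sprintf(
      "%d call(s) with missing n_snps kept despite min_snps = %d",
      sum(missing), min_snps), call. = FALSE)
  }
  keep <- missing | calls$n_snps >= min_snps
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Collapse each subject's calls on one chromosome into maximal covering
# intervals so that the sweep counter counts subjects, not calls (state is
# irrelevant here; assign_states goes back to the original calls). Under
# half-open coverage, [s1,e1] and [s2,e2] with s2 <= e1 merge into one
# covering interval. 1-bp calls (start == end) cover nothing and are
# dropped. `classes`, when given, separates losses from gains.
subject_intervals <- function(calls, by_class = FALSE) {
  if (nrow(calls) == 0L) {
    return(data.frame(subject_id = character(), chromosome = character(),
                      start = numeric(), end = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  }
  cls <- if (by_class) ifelse(calls$dose < 0, "loss", "gain") else "any"
  df <- data.frame(subject_id = calls$subject_id,
                   chromosome = calls$chromosome,
                   start = calls$start, end = calls$end,
                   class = cls, stringsAsFactors = FALSE)
  df <- df[df$end > df$start, , drop = FALSE]  # 1-bp calls cover no segment
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$chromosome, df$class, df$subject_id, df$start, df$end), ,
           drop = FALSE]
  key <- paste(df$chromosome, df$class, df$subject_id, sep = "\r")
  g <- match(key, unique(key))
  n <- nrow(df)
  # running max of interval ends within each (chrom, class, subject) group;
  # a new covering interval starts where the next start exceeds it
  cme <- stats::ave(df$end, g, FUN = cummax)
  new_group <- c(TRUE, g[-1] != g[-n])
  new_run <- new_group | df$start > c(-Inf, cme[-n])
  run_last <- c(which(new_run)[-1] - 1L, n)
  out <- data.frame(subject_id = df$subject_id[new_run],
                    chromosome = df$chromosome[new_run],
                    start = df$start[new_run], end = cme[run_last],
                    class = df$class[new_run], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Piecewise-constant carrier-count profile of one chromosome
#'
#' Brute-force enumeration of the coverage profile: for every segment
#' between consecutive distinct event positions (call starts and ends), the
#' number of distinct subjects with a call covering the segment is counted
#' directly. The profile is the reference implementation against which the
#' one-pass sweep of [detect_sub_cnvrs()] is verified, and it powers the
#' per-chromosome region-distribution summary.
#'
#' @param calls a `cnv_calls` data frame restricted to (or filtered here
#'   by) one chromosome.
#' @param chromosome chromosome label.
#' @return data frame with `start`, `end` (event positions; the segment is
#'   `[start, end)`), `count` (distinct carriers) and `length` (`end -
#'   start`). Empty input gives an empty profile.
#' @export
coverage_profile <- function(calls, chromosome) {
  calls <- calls[calls$chromosome == chromosome, , drop = FALSE]
  calls <- calls[calls$end > calls$start, , drop = FALSE]
  if (nrow(calls) == 0L) {
    return(data.frame(start = numeric(), end = numeric(),
                      count = integer(), length = numeric()))
  }
  pos <- sort(unique(c(calls$start, calls$end)))
  n_seg <- length(pos) - 1L
  # direct enumeration: call x segment coverage indicator, collapsed to
  # distinct subjects per segment
  covering <- outer(calls$start, pos[-length(pos)], "<=") &
    outer(calls$end, pos[-1], ">=")
  by_subject <- rowsum(covering + 0, calls$subject_id) > 0
  data.frame(start = pos[-length(pos)], end = pos[-1],
             count = as.integer(colSums(by_subject)), length = diff(pos))
}

new_sub_cnvr_table <- function(df, n_subjects, cfg) {
  rownames(df) <- NULL
  attr(df, "n_subjects") <- n_subjects
  attr(df, "freq_threshold") <- cfg$freq_threshold
  class(df) <- c("sub_cnvr_table", "data.frame")
  df
}

empty_sub_cnvr_table <- function(n_subjects, cfg) {
  new_sub_cnvr_table(data.frame(
    region_id = character(), chromosome = character(),
    start = numeric(), end = numeric(),
    n_carriers = integer(), frequency = numeric(),
    state_class = character(),
    carriers = I(list()), stringsAsFactors = FALSE), n_subjects, cfg)
}

#' @export
print.sub_cnvr_table <- function(x, ...) {
  cat(sprintf(
    "sub-CNVRs: %d region(s) above frequency threshold %g (n = %d subjects)\n",
    nrow(x), attr(x, "freq_threshold"), attr(x, "n_subjects")))
  cols <- setdiff(names(x), "carriers")
  print.data.frame(head(as.data.frame(x)[cols], 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# One-pass sweep over one chromosome: segment boundaries sit at every
# distinct border SNP of the individual calls (so a potential sub-CNVR
# begins wherever any CNV begins or ends, exactly as the sorted event list
# prescribes), while the counter increments/decrements on the per-subject
# covering intervals so that it counts subjects, not calls. All events at
# one physical position are applied before any segment is evaluated.
sweep_chromosome <- function(iv, raw_pos, chrom, cls, n_subjects, thr) {
  iv <- iv[iv$chromosome == chrom & iv$class == cls, , drop = FALSE]
  if (nrow(iv) == 0L) return(NULL)
  upos <- raw_pos  # sorted distinct border positions of the raw calls
  add <- tabulate(match(iv$start, upos), length(upos))
  rem <- tabulate(match(iv$end, upos), length(upos))
  cnt <- cumsum(add - rem)
  n_seg <- length(upos) - 1L
  if (n_seg < 1L) return(NULL)
  seg_cnt <- cnt[seq_len(n_seg)]
  above <- which(seg_cnt / n_subjects > thr)
  if (length(above) == 0L) return(NULL)
  res <- lapply(above, function(k) {
    carriers <- sort(unique(
      iv$subject_id[iv$start <= upos[k] & iv$end >= upos[k + 1L]]))
    stopifnot(length(carriers) == seg_cnt[k])
    data.frame(chromosome = chrom, start = upos[k], end = upos[k + 1L],
               n_carriers = seg_cnt[k],
               frequency = seg_cnt[k] / n_subjects,
               state_class = cls,
               carriers = I(list(carriers)), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Detect sub-CNVRs with the sweep-line counter (basic algorithm)
#'
#' For each chromosome, the borders of all calls are collected into a
#' sorted event list; a counter increments on each CNV-starting SNP and
#' decrements on each CNV-ending SNP, with all events at one physical
#' position applied before any segment is evaluated. Every segment between
#' consecutive distinct event positions whose carrier frequency (distinct
#' carrying subjects divided by `n_subjects`) is strictly greater than
#' `cfg$freq_threshold` is reported as one sub-CNVR, bracketed by its
#' opening and closing event positions. Before counting, each subject's
#' overlapping calls are collapsed into maximal covering intervals so the
#' counter counts subjects (the frequency definition), not calls.
#'
#' Region boundaries are only approximations: they are the physical
#' positions of the bracketing SNPs, not of the true variant breakpoints.
#'
#' @param calls a `cnv_calls` data frame (any row order; output is
#'   independent of it).
#' @param n_subjects total number of subjects in the study (the frequency
#'   denominator) - not merely the number of subjects with calls.
#' @param cfg a [detection_config()].
#' @param snp_map optional SNP map; when given, calls on chromosomes absent
#'   from the map are an error.
#' @return a `sub_cnvr_table`: `region_id`, `chromosome`, `start`, `end`,
#'   `n_carriers`, `frequency`, `state_class` ("any", or "loss"/"gain" when
#'   `pool_states = FALSE`) and the list column `carriers`; sorted by
#'   (chromosome, start). Attributes `n_subjects` and `freq_threshold`.
#' @examples
#' calls <- data.frame(
#'   subject_id = c("A", "B", "C"), chromosome = "1",
#'   start = c(100, 200, 200), end = c(300, 400, 300),
#'   state = "1", dose = -1, n_snps = 10L,
#'   start_marker = NA, end_marker = NA)
#' detect_sub_cnvrs(calls, n_subjects = 4, detection_config(0.5))
#' @export
detect_sub_cnvrs <- function(calls, n_subjects, cfg = detection_config(),
                             snp_map = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    cnv_stop("n_subjects must be a positive integer")
  }
  if (!inherits(cfg, "detection_config")) cnv_stop("cfg must be a detection_config")
  if (!is.null(snp_map)) {
    unknown <- setdiff(unique(calls$chromosome), unique(snp_map$chromosome))
    if (length(unknown)) {
      cnv_stop(sprintf("call chromosome(s) absent from the SNP map: %s",
                       paste(unknown, collapse = ", ")))
    }
  }
  if (nrow(calls) == 0L) return(empty_sub_cnvr_table(n_subjects, cfg))
  iv <- subject_intervals(calls, by_class = !cfg$pool_states)
  if (nrow(iv) == 0L) return(empty_sub_cnvr_table(n_subjects, cfg))
  covering <- calls[calls$end > calls$start, , drop = FALSE]
  call_class <- if (cfg$pool_states) rep("any", nrow(covering)) else
    ifelse(covering$dose < 0, "loss", "gain")
  chroms <- chrom_levels(iv$chromosome)
  classes <- sort(unique(iv$class))
  pieces <- list()
  for (chrom in chroms) {
    for (cls in classes) {
      sel <- covering$chromosome == chrom & call_class == cls
      raw_pos <- sort(unique(c(covering$start[sel], covering$end[sel])))
      piece <- sweep_chromosome(iv, raw_pos, chrom, cls, n_subjects,
                                cfg$freq_threshold)
      if (!is.null(piece)) pieces[[length(pieces) + 1L]] <- piece
    }
  }
  if (length(pieces) == 0L) return(empty_sub_cnvr_table(n_subjects, cfg))
  out <- do.call(rbind, pieces)
  out <- out[order(chrom_factor(out$chromosome), out$start, out$state_class), ,
             drop = FALSE]
  out$region_id <- sprintf("%s:%s-%s%s", out$chromosome,
                           format(out$start, scientific = FALSE, trim = TRUE),
                           format(out$end, scientific = FALSE, trim = TRUE),
                           ifelse(out$state_class == "any", "",
                                  paste0(":", out$state_class)))
  out <- out[, c("region_id", "chromosome", "start", "end", "n_carriers",
                 "frequency", "state_class", "carriers")]
  new_sub_cnvr_table(out, n_subjects, cfg)
}
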