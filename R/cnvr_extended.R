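# Extended algorithm: merge consecutive sub-CNVRs and assign per-subject
# states. With many subjects and highly interlaced CNVs, the basic
# detector yields a multitude of regions only two SNPs long; merging
# consecutive above-threshold sub-CNVRs produces regions of useful length,
# at the price that a subject's state in a merged region is no longer
# unique - a second threshold on the overlap of the subject's longest CNV
# then defines the state.

new_cnvr_table <- function(df, n_subjects, cfg) {
  rownames(df) <- NULL
  attr(df, "n_subjects") <- n_subjects
  attr(df, "freq_threshold") <- cfg$freq_threshold %||% NA_real_
  class(df) <- c("cnvr_table", "data.frame")
  df
}

#' @export
print.cnvr_table <- function(x, ...) {
  cat(sprintf("CNV regions: %d region(s) (n = %s subjects)\n", nrow(x),
              attr(x, "n_subjects") %||% "?"))
  cols <- setdiff(names(x), c("carriers", "members"))
  print.data.frame(head(as.data.frame(x)[cols], 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Merge consecutive sub-CNVRs into CNV regions (extended algorithm)
#'
#' Two sub-CNVRs on the same chromosome (and of the same state class) are
#' merged when they share a bracketing event position, i.e. when no
#' below-threshold segment lies between them; maximal chains of such
#' regions become one merged region. Every input region is a member of
#' exactly one output region, so `count(output) <= count(input)` and
#' [split_cnvrs()] recovers the input exactly.
#'
#' The frequency of a merged region is recomputed over the merged span as
#' the fraction of distinct subjects carrying a CNV anywhere inside it
#' (which is the union of the member carrier sets); member frequencies are
#' retained in the `members` list column.
#'
#' @param sub_cnvrs a `sub_cnvr_table` from [detect_sub_cnvrs()] (already
#'   above-threshold and sorted; unsorted input is a contract violation).
#' @return a `cnvr_table`: `region_id`, `chromosome`, `start`, `end`,
#'   `region_length` (`end - start + 1`), `n_members`, `n_carriers`,
#'   `frequency`, `state_class`, plus list columns `carriers` and `members`
#'   (each member a one-row data frame of the input).
#' @export
merge_sub_cnvrs <- function(sub_cnvrs) {
  n_subjects <- attr(sub_cnvrs, "n_subjects")
  cfg <- list(freq_threshold = attr(sub_cnvrs, "freq_threshold"))
  if (nrow(sub_cnvrs) == 0L) {
    return(new_cnvr_table(data.frame(
      region_id = character(), chromosome = character(),
      start = numeric(), end = numeric(), region_length = numeric(),
      n_members = integer(), n_carriers = integer(), frequency = numeric(),
      state_class = character(), carriers = I(list()), members = I(list()),
      stringsAsFactors = FALSE), n_subjects, cfg))
  }
  cf <- chrom_factor(sub_cnvrs$chromosome)
  o <- order(cf, sub_cnvrs$state_class, sub_cnvrs$start)
  grp_sorted <- order(cf, sub_cnvrs$start, sub_cnvrs$state_class)
  if (!identical(grp_sorted, seq_len(nrow(sub_cnvrs)))) {
    cnv_stop("sub-CNVRs must be sorted by (chromosome, start) as produced by detect_sub_cnvrs")
  }
  x <- sub_cnvrs[o, , drop = FALSE]
  same_chain <- c(FALSE,
    x$chromosome[-1] == x$chromosome[-nrow(x)] &
    x$state_class[-1] == x$state_class[-nrow(x)] &
    x$start[-1] == x$end[-nrow(x)])
  chain <- cumsum(!same_chain)
  pieces <- lapply(split(seq_len(nrow(x)), chain), function(idx) {
    m <- x[idx, , drop = FALSE]
    carriers <- sort(unique(unlist(m$carriers)))
    data.frame(chromosome = m$chromosome[1],
               start = min(m$start), end = max(m$end),
               region_length = max(m$end) - min(m$start) + 1,
               n_members = length(idx),
               n_carriers = length(carriers),
               frequency = if (is.null(n_subjects)) NA_real_ else
                 length(carriers) / n_subjects,
               state_class = m$state_class[1],
               carriers = I(list(carriers)),
               members = I(list(m)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(chrom_factor(out$chromosome), out$start, out$state_class), ,
             drop = FALSE]
  out$region_id <- sprintf("%s:%s-%s%s", out$chromosome,
                           format(out$start, scientific = FALSE, trim = TRUE),
                           format(out$end, scientific = FALSE, trim = TRUE),
                           ifelse(out$state_class == "any", "",
                                  paste0(":", out$state_class)))
  out <- out[, c("region_id", "chromosome", "start", "end", "region_length",
                 "n_members", "n_carriers", "frequency", "state_class",
                 "carriers", "members")]
  new_cnvr_table(out, n_subjects, cfg)
}

#' Split merged regions back into their member sub-CNVRs
#'
#' Inverse of [merge_sub_cnvrs()]: concatenating the member rows of every
#' merged region recovers the basic detector's output exactly.
#'
#' @param cnvrs a `cnvr_table` from [merge_sub_cnvrs()].
#' @return a `sub_cnvr_table`.
#' @export
split_cnvrs <- function(cnvrs) {
  n_subjects <- attr(cnvrs, "n_subjects")
  cfg <- list(freq_threshold = attr(cnvrs, "freq_threshold"))
  if (nrow(cnvrs) == 0L || is.null(cnvrs$members)) {
    return(empty_sub_cnvr_table(n_subjects, cfg))
  }
  out <- do.call(rbind, cnvrs$members)
  out <- out[order(chrom_factor(out$chromosome), out$start, out$state_class), ,
             drop = FALSE]
  new_sub_cnvr_table(out, n_subjects, cfg)
}

# Promote unmerged sub-CNVRs to a region table so that downstream state
# assignment and association treat basic and extended output uniformly.
as_cnvr_table <- function(sub_cnvrs) {
  n_subjects <- attr(sub_cnvrs, "n_subjects")
  cfg <- list(freq_threshold = attr(sub_cnvrs, "freq_threshold"))
  df <- as.data.frame(sub_cnvrs)
  df$region_length <- df$end - df$start + 1
  df$n_members <- rep(1L, nrow(df))
  df$members <- I(lapply(seq_len(nrow(sub_cnvrs)), function(i) {
    sub_cnvrs[i, , drop = FALSE]
  }))
  df <- df[, c("region_id", "chromosome", "start", "end", "region_length",
               "n_members", "n_carriers", "frequency", "state_class",
               "carriers", "members")]
  new_cnvr_table(df, n_subjects, cfg)
}

#' Assign one copy-number state per subject and region
#'
#' For every subject, among that subject's calls overlapping the region the
#' call with the longest overlap is selected (ties broken toward the larger
#' absolute dose, then the leftmost start - deterministic). If its overlap
#' exceeds `state_len_threshold` as a fraction of the region length
#' (strictly; or, with `cfg$state_len_bp` set, exceeds that many bp), the
#' subject's state is that call's signed dose; otherwise 0 (no qualifying
#' CNV). Region length is `end - start + 1` (1-based closed span).
#'
#' @param regions a `cnvr_table` (or any data frame with `region_id`,
#'   `chromosome`, `start`, `end`, `region_length`).
#' @param calls the original `cnv_calls` (states intact).
#' @param cfg a [detection_config()].
#' @param subjects character vector of all study subjects (columns of the
#'   result).
#' @return numeric matrix, regions x subjects, of signed-dose states
#'   (0 = no qualifying CNV).
#' @export
assign_states <- function(regions, calls, cfg = detection_config(),
                          subjects) {
  if (missing(subjects) || length(subjects) == 0L) {
    cnv_stop("subjects must be given")
  }
  region_length <- regions$region_length %||% (regions$end - regions$start + 1)
  if (any(region_length <= 0)) cnv_stop("region with non-positive length")
  states <- matrix(0, nrow(regions), length(subjects),
                   dimnames = list(regions$region_id, subjects))
  if (nrow(regions) == 0L || nrow(calls) == 0L) return(states)
  calls <- calls[calls$subject_id %in% subjects, , drop = FALSE]
  for (i in seq_len(nrow(regions))) {
    ov <- calls[calls$chromosome == regions$chromosome[i] &
                calls$end >= regions$start[i] &
                calls$start <= regions$end[i], , drop = FALSE]
    if (nrow(ov) == 0L) next
    overlap <- pmin(ov$end, regions$end[i]) - pmax(ov$start, regions$start[i]) + 1
    ord <- order(ov$subject_id, -overlap, -abs(ov$dose), ov$start, -ov$dose)
    first <- ord[!duplicated(ov$subject_id[ord])]
    qual <- if (!is.null(cfg$state_len_bp)) {
      overlap[first] > cfg$state_len_bp
    } else {
      overlap[first] / region_length[i] > cfg$state_len_threshold
    }
    hit <- first[qual]
    if (length(hit)) states[i, ov$subject_id[hit]] <- ov$dose[hit]
  }
  states
}

#' Detect CNV regions and assign subject states (high-level wrapper)
#'
#' Runs the full detection pipeline: minimum-SNP filtering, sweep-line
#' sub-CNVR detection, optional merging of consecutive sub-CNVRs
#' (`cfg$merge`), and per-subject state assignment.
#'
#' @inheritParams detect_sub_cnvrs
#' @param subjects character vector of all study subjects; defaults to the
#'   subjects present in `calls` (supply the full cohort explicitly when
#'   some subjects have no calls, so frequencies use the right denominator).
#' @return list with `regions` (a `cnvr_table`), `states` (regions x
#'   subjects matrix), `sub_cnvrs` (the basic detector's output) and
#'   `config`.
#' @export
detect_cnvrs <- function(calls, n_subjects = NULL, cfg = detection_config(),
                         subjects = NULL, snp_map = NULL) {
  subjects <- subjects %||% sort(unique(calls$subject_id))
  n_subjects <- n_subjects %||% length(subjects)
  kept <- filter_min_snps(calls, cfg$min_snps)
  sub <- detect_sub_cnvrs(kept, n_subjects, cfg, snp_map = snp_map)
  regions <- if (cfg$merge) merge_sub_cnvrs(sub) else as_cnvr_table(sub)
  states <- assign_states(regions, kept, cfg, subjects)
  list(regions = regions, states = states, sub_cnvrs = sub, config = cfg)
}
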