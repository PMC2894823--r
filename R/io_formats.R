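# Readers and writers for every external format the tool touches.
# All coordinates are stored 1-based with closed intervals regardless of
# source dialect; every rejected row carries a file line number so that
# rows_in == rows_parsed + rows_rejected always holds.

GENERIC_CNV_COLUMNS <- c("subject_id", "chromosome", "start", "end",
                         "state", "n_snps")

new_cnv_calls <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("CNV calls: %d call(s), %d subject(s), %d chromosome(s)\n",
              nrow(x), length(unique(x$subject_id)),
              length(unique(x$chromosome))))
  print.data.frame(head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# Resolve a position column that may hold bp positions or marker ids.
resolve_positions <- function(values, snp_map, what, lines) {
  v <- suppressWarnings(as.numeric(values))
  markers <- rep(NA_character_, length(values))
  if (anyNA(v)) {
    idx <- which(is.na(v))
    if (is.null(snp_map)) {
      cnv_stop(sprintf(
        "non-numeric %s position %s at line %d (no SNP map given to resolve marker ids)",
        what, sQuote(values[idx[1]]), lines[idx[1]]))
    }
    hit <- match(values[idx], snp_map$marker_id)
    if (anyNA(hit)) {
      miss <- idx[is.na(hit)][1]
      cnv_stop(sprintf("unknown marker id %s in column %s at line %d",
                       sQuote(values[miss]), sQuote(what), lines[miss]))
    }
    v[idx] <- snp_map$position[hit]
    markers[idx] <- values[idx]
  }
  if (any(v < 1, na.rm = TRUE)) {
    bad <- which(v < 1)[1]
    cnv_stop(sprintf("position < 1 in column %s at line %d", what, lines[bad]))
  }
  list(pos = v, marker = markers)
}

validate_call_table <- function(df, lines) {
  bad <- which(df$end < df$start)
  if (length(bad)) {
    cnv_stop(sprintf("end < start at line %d (subject %s)",
                     lines[bad[1]], sQuote(df$subject_id[bad[1]])))
  }
  if (any(!is.na(df$n_snps) & df$n_snps < 1)) {
    bad <- which(!is.na(df$n_snps) & df$n_snps < 1)[1]
    cnv_stop(sprintf("n_snps < 1 at line %d", lines[bad]))
  }
  invisible(df)
}

#' Read CNV calls from the generic CSV interchange format
#'
#' The canonical interchange dialect is a CSV with header
#' `subject_id,chromosome,start,end,state,n_snps` and one CNV call per row.
#' Coordinates are 1-based closed base-pair positions; alternatively, when a
#' SNP map is supplied, `start`/`end` may hold marker ids which are resolved
#' to the marker positions. `state` uses the vocabulary of
#' [normalize_state()]. `n_snps` is the number of array probes supporting
#' the segment and may be empty (such calls are exempted from the minimum
#' SNP filter, with a warning downstream).
#'
#' @param path path to a CSV file.
#' @param snp_map optional SNP map (data frame with `marker_id`,
#'   `chromosome`, `position`) used to resolve marker ids to positions.
#' @return a `cnv_calls` data frame with columns `subject_id`, `chromosome`,
#'   `start`, `end`, `state` (as given), `dose` (normalized signed dose),
#'   `n_snps`, `start_marker`, `end_marker`.
#' @seealso [write_generic_cnv_csv()], [read_segment_summary()]
#' @export
read_generic_cnv_csv <- function(path, snp_map = NULL) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing <- setdiff(GENERIC_CNV_COLUMNS, names(raw))
  if (length(missing)) {
    cnv_stop(sprintf("missing required column(s): %s",
                     paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    return(new_cnv_calls(data.frame(
      subject_id = character(), chromosome = character(),
      start = numeric(), end = numeric(), state = character(),
      dose = numeric(), n_snps = integer(),
      start_marker = character(), end_marker = character(),
      stringsAsFactors = FALSE)))
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1

  st <- resolve_positions(raw$start, snp_map, "start", lines)
  en <- resolve_positions(raw$end, snp_map, "end", lines)
  n_snps <- suppressWarnings(as.integer(raw$n_snps))
  bad_n <- nzchar(trimws(raw$n_snps)) & is.na(n_snps)
  if (any(bad_n)) {
    cnv_stop(sprintf("non-integer n_snps %s at line %d",
                     sQuote(raw$n_snps[which(bad_n)[1]]),
                     lines[which(bad_n)[1]]))
  }
  df <- data.frame(
    subject_id = raw$subject_id,
    chromosome = raw$chromosome,
    start = st$pos, end = en$pos,
    state = trimws(raw$state),
    dose = normalize_state(raw$state),
    n_snps = n_snps,
    start_marker = st$marker, end_marker = en$marker,
    stringsAsFactors = FALSE)
  validate_call_table(df, lines)
  new_cnv_calls(df)
}

#' Write CNV calls in the generic CSV interchange format
#'
#' @param calls a `cnv_calls` data frame (see [read_generic_cnv_csv()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_generic_cnv_csv <- function(calls, path) {
  out <- data.frame(
    subject_id = calls$subject_id,
    chromosome = calls$chromosome,
    start = format(calls$start, scientific = FALSE, trim = TRUE),
    end = format(calls$end, scientific = FALSE, trim = TRUE),
    state = calls$state,
    n_snps = ifelse(is.na(calls$n_snps), "", as.character(calls$n_snps)),
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Header synonyms of the segment-summary dialect. The layout of the
# Genotyping Console "Copy Number Segment Summary" export is not publicly
# documented; this reader is a tolerant reconstruction that matches on
# case- and punctuation-insensitive column names.
SEGMENT_SUMMARY_SYNONYMS <- list(
  subject_id = c("sample", "sampleid", "samplename", "subject", "subjectid"),
  chromosome = c("chromosome", "chr", "chrom"),
  start      = c("start", "startposition", "startpos", "segmentstart"),
  end        = c("end", "endposition", "endpos", "segmentend"),
  state      = c("cnstate", "copynumberstate", "copynumber", "state", "cn"),
  n_snps     = c("markercount", "nmarkers", "nummarkers", "probecount",
                 "markers", "nsnps"))

canon_header <- function(h) gsub("[^a-z0-9]", "", tolower(h))

#' Read CNV calls from a Genotyping Console segment-summary export
#'
#' Tolerant adapter for per-segment "Copy Number Segment Summary" style
#' tables (tab-, comma- or semicolon-delimited) with one segment per row:
#' sample, chromosome, start/end position, copy-number state, and marker
#' count. Column names are matched against a synonym list
#' case-insensitively, ignoring spaces and punctuation. The exact layout of
#' the proprietary export is not publicly documented, so this dialect is a
#' reconstruction; the generic CSV of [read_generic_cnv_csv()] is the
#' canonical interchange format.
#'
#' Rows with copy number 2 are rejected with a warning (a neutral segment is
#' not a CNV); rejected rows are reported in the `rejections` attribute with
#' their line numbers, so no row is ever silently dropped. A missing
#' marker-count column yields `n_snps = NA` with a warning; such calls pass
#' the minimum-SNP filter unexamined.
#'
#' @inheritParams read_generic_cnv_csv
#' @return a `cnv_calls` data frame (see [read_generic_cnv_csv()]) with
#'   attribute `rejections`: a data frame of `line` and `reason`.
#' @export
read_segment_summary <- function(path) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  delim <- detect_delim(path)
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  canon <- canon_header(names(raw))
  idx <- lapply(SEGMENT_SUMMARY_SYNONYMS, function(syn) {
    which(canon %in% syn)[1]
  })
  required <- c("subject_id", "chromosome", "start", "end", "state")
  miss <- required[vapply(idx[required], is.na, logical(1))]
  if (length(miss)) {
    cnv_stop(sprintf(
      "unrecognized segment-summary header; could not find column(s) %s (accepted synonyms: %s)",
      paste(miss, collapse = ", "),
      paste(vapply(miss, function(m) {
        paste(SEGMENT_SUMMARY_SYNONYMS[[m]], collapse = "/")
      }, character(1)), collapse = "; ")))
  }
  has_nsnps <- !is.na(idx$n_snps)
  if (!has_nsnps) {
    warning("segment summary has no marker-count column; n_snps set to NA ",
            "(such calls are exempt from the minimum-SNP filter)",
            call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    out <- read_generic_cnv_csv_empty()
    attr(out, "rejections") <- data.frame(line = integer(),
                                          reason = character())
    return(out)
  }
  lines <- seq_len(nrow(raw)) + 1L
  state_raw <- trimws(raw[[idx$state]])

  neutral <- suppressWarnings(as.numeric(state_raw)) == 2 &
    !grepl("^[+-]", state_raw)
  neutral[is.na(neutral)] <- FALSE
  if (any(neutral)) {
    warning(sprintf(
      "%d segment(s) with neutral state CN=2 rejected (not a CNV)",
      sum(neutral)), call. = FALSE)
  }
  keep <- !neutral
  rejections <- data.frame(line = lines[neutral],
                           reason = rep("neutral state (CN=2)", sum(neutral)),
                           stringsAsFactors = FALSE)

  st <- resolve_positions(raw[[idx$start]][keep], NULL, "start", lines[keep])
  en <- resolve_positions(raw[[idx$end]][keep], NULL, "end", lines[keep])
  n_snps <- if (has_nsnps) {
    suppressWarnings(as.integer(raw[[idx$n_snps]][keep]))
  } else {
    rep(NA_integer_, sum(keep))
  }
  df <- data.frame(
    subject_id = raw[[idx$subject_id]][keep],
    chromosome = raw[[idx$chromosome]][keep],
    start = st$pos, end = en$pos,
    state = state_raw[keep],
    dose = normalize_state(state_raw[keep]),
    n_snps = n_snps,
    start_marker = NA_character_, end_marker = NA_character_,
    stringsAsFactors = FALSE)
  validate_call_table(df, lines[keep])
  out <- new_cnv_calls(df)
  attr(out, "rejections") <- rejections
  out
}

read_generic_cnv_csv_empty <- function() {
  new_cnv_calls(data.frame(
    subject_id = character(), chromosome = character(),
    start = numeric(), end = numeric(), state = character(),
    dose = numeric(), n_snps = integer(),
    start_marker = character(), end_marker = character(),
    stringsAsFactors = FALSE))
}

#' Write CNV calls in the segment-summary dialect
#'
#' Writes the tab-delimited per-segment table understood by
#' [read_segment_summary()], with copy-number states (signed doses are
#' converted back via [dose_to_cn()]).
#'
#' @inheritParams write_generic_cnv_csv
#' @export
write_segment_summary <- function(calls, path) {
  out <- data.frame(
    Sample = calls$subject_id,
    Chromosome = calls$chromosome,
    `Start Position` = format(calls$start, scientific = FALSE, trim = TRUE),
    `End Position` = format(calls$end, scientific = FALSE, trim = TRUE),
    `CN State` = dose_to_cn(calls$dose),
    `Marker Count` = ifelse(is.na(calls$n_snps), "",
                            as.character(calls$n_snps)),
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SNP map
#'
#' A SNP map is a CSV with header `marker_id,chromosome,position` giving the
#' 1-based bp position of every array marker. Marker ids must be unique.
#'
#' @param path path to the CSV file.
#' @return data frame with columns `marker_id`, `chromosome`, `position`,
#'   sorted by (chromosome, position).
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  df <- read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("marker_id", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    cnv_stop(sprintf("SNP map missing column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  pos <- suppressWarnings(as.numeric(df$position))
  if (anyNA(pos)) {
    cnv_stop(sprintf("non-numeric position at line %d",
                     which(is.na(pos))[1] + 1L))
  }
  if (anyDuplicated(df$marker_id)) {
    cnv_stop(sprintf("duplicate marker id %s",
                     sQuote(df$marker_id[anyDuplicated(df$marker_id)])))
  }
  if (any(pos < 1)) cnv_stop("SNP positions must be >= 1")
  out <- data.frame(marker_id = df$marker_id, chromosome = df$chromosome,
                    position = pos, stringsAsFactors = FALSE)
  out[order(chrom_factor(out$chromosome), out$position), , drop = FALSE]
}

#' Write a SNP map
#' @param snp_map data frame with `marker_id`, `chromosome`, `position`.
#' @param path output path.
#' @export
write_snp_map <- function(snp_map, path) {
  out <- snp_map[, c("marker_id", "chromosome", "position")]
  out$position <- format(out$position, scientific = FALSE, trim = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Phenotypes are stored in a CSV in which each row is one subject: the
#' first column holds the subject id, every other column a numeric
#' phenotype. The import validates that only numerical values are contained;
#' empty cells become explicit missing values (never zero), and a subject is
#' excluded only from analyses that use the affected column.
#'
#' @param path path to the CSV file.
#' @return a `phenotype_table` data frame: `subject_id` plus numeric columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  delim <- detect_delim(path)
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  if (ncol(raw) < 2L) cnv_stop("phenotype table needs a subject id column and at least one phenotype column")
  names(raw)[1] <- "subject_id"
  if (anyDuplicated(names(raw))) cnv_stop("duplicate phenotype column names")
  dup <- raw$subject_id[duplicated(raw$subject_id)]
  if (length(dup)) {
    cnv_stop(sprintf("duplicate subject id %s", sQuote(dup[1])))
  }
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  for (col in names(raw)[-1]) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- nzchar(vals) & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      cnv_stop(sprintf(
        "non-numeric value %s in phenotype column %s (subject %s, line %d)",
        sQuote(vals[i]), sQuote(col), sQuote(raw$subject_id[i]), i + 1L))
    }
    out[[col]] <- num
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table
#' @param phenos a `phenotype_table` data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(phenos, path) {
  out <- as.data.frame(phenos)
  for (col in names(out)[-1]) out[[col]] <- num_to_text(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Genotype call codes of the ".call"-style table: letter codes or the
# numeric Affymetrix codes (-1 = NoCall, 0 = AA, 1 = AB, 2 = BB).
GENOTYPE_CODE_MAP <- c(AA = 0, AB = 1, BA = 1, BB = 2,
                       `0` = 0, `1` = 1, `2` = 2)
GENOTYPE_MISSING_CODES <- c("NOCALL", "NC", "NN", "-1", "NA", "")

#' Read a genotype call table
#'
#' Reads a markers-by-subjects SNP genotype table in the ".call" style: the
#' first column holds the marker (probeset) id, every other column one
#' subject. Calls may be letter codes (`AA`, `AB`, `BB`, `NoCall`) or the
#' numeric codes `0`/`1`/`2`/`-1`; both are mapped to the additive B-allele
#' dose \{0, 1, 2\} with `NoCall`/`-1` as missing.
#'
#' @param path path to a tab- or comma-delimited table.
#' @return numeric dose matrix, markers in rows (rownames = marker ids),
#'   subjects in columns.
#' @export
read_genotype_calls <- function(path) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  delim <- detect_delim(path)
  fields <- count.fields(path, sep = delim, quote = "\"")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1])[1]
    cnv_stop(sprintf(
      "ragged genotype table: line %d has %d field(s), expected %d",
      bad, fields[bad], fields[1]))
  }
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  if (ncol(raw) < 2L) cnv_stop("genotype table needs a marker column and at least one subject column")
  markers <- raw[[1]]
  if (anyDuplicated(markers)) {
    cnv_stop(sprintf("duplicate marker id %s",
                     sQuote(markers[duplicated(markers)][1])))
  }
  subjects <- names(raw)[-1]
  doses <- matrix(NA_real_, nrow(raw), length(subjects),
                  dimnames = list(markers, subjects))
  for (j in seq_along(subjects)) {
    code <- toupper(trimws(raw[[j + 1L]]))
    missing <- code %in% GENOTYPE_MISSING_CODES
    known <- code %in% names(GENOTYPE_CODE_MAP)
    bad <- !missing & !known
    if (any(bad)) {
      i <- which(bad)[1]
      cnv_stop(sprintf(
        "unknown genotype code %s at marker %s, subject %s",
        sQuote(raw[[j + 1L]][i]), sQuote(markers[i]), sQuote(subjects[j])))
    }
    v <- rep(NA_real_, length(code))
    v[known] <- unname(GENOTYPE_CODE_MAP[code[known]])
    doses[, j] <- v
  }
  doses
}

#' Write a genotype call table
#'
#' Writes a dose matrix as a tab-delimited `.call`-style table with letter
#' codes (`AA`/`AB`/`BB`, missing as `NoCall`).
#'
#' @param doses numeric dose matrix (markers x subjects).
#' @param path output path.
#' @export
write_genotype_calls <- function(doses, path) {
  codes <- matrix(c("AA", "AB", "BB")[doses + 1L], nrow(doses),
                  dimnames = dimnames(doses))
  codes[is.na(doses)] <- "NoCall"
  out <- data.frame(probeset_id = rownames(doses), codes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a known-association catalog
#'
#' A catalog of published trait-associated regions, as a 4-column BED-like
#' file `chrom,start,end,trait` (comma- or tab-delimited, with or without a
#' header line). Files ending in `.bed` default to BED semantics (0-based
#' half-open) and are converted to the internal 1-based closed convention;
#' all other files default to 1-based closed.
#'
#' @param path path to the catalog file.
#' @param coords `"auto"` (by file extension), `"bed"` (0-based half-open)
#'   or `"onebased"` (1-based closed).
#' @return data frame `chromosome`, `start`, `end`, `trait` (1-based closed).
#' @export
read_catalog <- function(path, coords = c("auto", "bed", "onebased")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  if (coords == "auto") {
    coords <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "onebased"
  }
  delim <- detect_delim(path)
  first <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  has_header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(first[2])))
  raw <- read.csv(path, sep = delim, header = has_header,
                  colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (ncol(raw) < 4L) cnv_stop("catalog needs 4 columns: chrom,start,end,trait")
  out <- data.frame(
    chromosome = sub("^chr", "", raw[[1]]),
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    trait = raw[[4]],
    stringsAsFactors = FALSE)
  if (coords == "bed") out$start <- out$start + 1
  if (any(out$end < out$start)) cnv_stop("catalog region with end < start")
  out
}

#' Cross-check CNV calls against a phenotype table
#'
#' Before an association run the subject sets of the two inputs are
#' compared: subjects present in the calls but not in the phenotypes (and
#' vice versa) are reported, and the analysis proceeds on the intersection.
#' An empty intersection is a fatal error.
#'
#' @param calls a `cnv_calls` data frame.
#' @param phenos a `phenotype_table` data frame.
#' @return list with `call_only`, `pheno_only`, `intersection`,
#'   `n_intersection`.
#' @export
validate_subject_consistency <- function(calls, phenos) {
  cs <- unique(calls$subject_id)
  ps <- unique(phenos$subject_id)
  inter <- intersect(cs, ps)
  if (length(inter) == 0L) {
    cnv_stop("no subject is present in both the CNV calls and the phenotype table")
  }
  list(call_only = setdiff(cs, ps),
       pheno_only = setdiff(ps, cs),
       intersection = inter,
       n_intersection = length(inter))
}

RESULT_NUMERIC_COLS <- c("start", "end", "region_length", "frequency", "n",
                         "beta", "se", "t", "p", "df", "position",
                         "beta_snp", "se_snp", "p_snp", "beta_state",
                         "se_state", "p_state", "f_joint", "df1", "df2",
                         "p_joint")

#' Write association results as CSV
#'
#' One row per tested region with its span, carrier frequency, sample size,
#' effect estimate, standard error, t statistic, p-value and the Bonferroni
#' significance flag (plus any covariate-effect and annotation columns
#' present). Numbers are serialized with 15 significant digits so a
#' read-back reproduces them to at least 12 significant digits; extreme
#' p-values (e.g. 1e-300) survive without underflow.
#'
#' @param results an `assoc_results` data frame from [run_gwas()] or
#'   [run_combined_snp_cnvr()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(results, path) {
  out <- as.data.frame(results)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) &&
        (col %in% RESULT_NUMERIC_COLS || grepl("^beta_", col))) {
      out[[col]] <- num_to_text(out[[col]])
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    cnv_stop(sprintf("cannot write results to %s: %s", path,
                     conditionMessage(e)))
  })
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read association results back from CSV
#'
#' @param path path written by [write_results_csv()].
#' @return an `assoc_results` data frame.
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 strip.white = TRUE)
  for (col in names(df)) {
    if (col %in% RESULT_NUMERIC_COLS || grepl("^beta_", col)) {
      df[[col]] <- as.numeric(ifelse(nzchar(df[[col]]), df[[col]], NA))
    }
    if (col %in% c("significant", "known_association")) {
      df[[col]] <- as.logical(df[[col]])
    }
  }
  class(df) <- c("assoc_results", "data.frame")
  df
}

#' Write detected regions as CSV (for reuse across studies)
#'
#' @param regions a `cnvr_table` data frame from [detect_cnvrs()] or
#'   [merge_sub_cnvrs()].
#' @param path output path.
#' @export
write_regions_csv <- function(regions, path) {
  out <- data.frame(
    region_id = regions$region_id,
    chromosome = regions$chromosome,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    region_length = regions$region_length,
    n_members = regions$n_members %||% 1L,
    n_carriers = regions$n_carriers,
    frequency = num_to_text(regions$frequency),
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detected regions from CSV
#' @param path path written by [write_regions_csv()].
#' @return a data frame of regions.
#' @export
read_regions_csv <- function(path) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  df <- read.csv(path, colClasses = "character", strip.white = TRUE)
  for (col in c("start", "end", "region_length", "n_members", "n_carriers",
                "frequency")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  class(df) <- c("cnvr_table", "data.frame")
  df
}

#' Write a region-by-subject state matrix as CSV
#' @param states numeric matrix (regions x subjects) from [assign_states()].
#' @param path output path.
#' @export
write_states_csv <- function(states, path) {
  out <- data.frame(region_id = rownames(states), states,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a region-by-subject state matrix from CSV
#' @param path path written by [write_states_csv()].
#' @return numeric matrix with region ids as rownames.
#' @export
read_states_csv <- function(path) {
  if (!file.exists(path)) cnv_stop(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Export regions as a BED file
#'
#' Converts the internal 1-based closed spans to BED's 0-based half-open
#' convention.
#'
#' @param regions a region table with `chromosome`, `start`, `end` and
#'   optionally `region_id`, `frequency`.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  name <- regions$region_id %||%
    sprintf("%s:%s-%s", regions$chromosome, regions$start, regions$end)
  score <- if (!is.null(regions$frequency)) {
    round(pmin(1, regions$frequency) * 1000)
  } else {
    rep(0L, nrow(regions))
  }
  out <- data.frame(chrom = regions$chromosome,
                    start = format(regions$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = name, score = score,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
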