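# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Raise a classed condition so the CLI can map validation problems (user
# errors, exit 1) apart from internal failures (exit 2).
cnv_stop <- function(msg, class = NULL) {
  stop(errorCondition(msg, class = c(class, "cnvrkit_error", "error")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Natural chromosome ordering
#'
#' Orders chromosome labels the way genome browsers do: autosomes by number
#' (1..22), then X, Y, MT; anything else alphabetically at the end. Accepts
#' labels with or without a "chr" prefix.
#'
#' @param chroms character vector of chromosome labels.
#' @return the unique labels in natural genomic order.
#' @examples
#' chrom_levels(c("2", "X", "1", "10"))
#' @export
chrom_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  stripped <- sub("^chr", "", u, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  special <- match(toupper(stripped), c("X", "Y", "MT", "M"))
  key <- ifelse(!is.na(num), num,
    ifelse(!is.na(special), 1000 + special, Inf))
  u[order(key, u)]
}

chrom_factor <- function(chroms) {
  factor(as.character(chroms), levels = chrom_levels(chroms))
}

# Detect the delimiter of a text table from its header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return(",")
  cands <- c(",", "\t", ";")
  counts <- vapply(cands, function(d) {
    length(gregexpr(d, header, fixed = TRUE)[[1]][
      gregexpr(d, header, fixed = TRUE)[[1]] > 0])
  }, integer(1))
  if (all(counts == 0L)) "," else cands[which.max(counts)]
}

# Significant-digit text for lossless-enough CSV round trips (12+ digits).
num_to_text <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}
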