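#' Normalize CNV state codes to a signed dose
#'
#' CNV callers report the copy-number status of a segment either as an
#' integer copy number (0, 1, 3, 4 on an autosomal diploid baseline) or as a
#' bare direction code (loss/gain). Internally every call carries one signed
#' numeric dose so that regions can enter an additive regression model with
#' a single column: CN0 -> -2, CN1 -> -1, CN3 -> +1, CN4 -> +2.
#'
#' The textual vocabulary is disambiguated by an explicit sign: values
#' written with a leading `+` or `-` ("+1", "-2") are already signed doses;
#' bare values ("0", "1", "3", "4") are copy numbers. A bare "2" is the
#' neutral diploid state and is rejected - a CNV call is by definition a
#' gain or a loss.
#'
#' @param state character or numeric vector of state codes.
#' @return numeric vector of signed doses in \{-2, -1, +1, +2\}.
#' @examples
#' normalize_state(c("0", "1", "3", "4"))   # copy numbers
#' normalize_state(c("-1", "+1"))           # sign codes
#' @export
normalize_state <- function(state) {
  s <- trimws(as.character(state))
  v <- suppressWarnings(as.numeric(s))
  if (anyNA(v) || any(!nzchar(s))) {
    bad <- unique(s[is.na(v) | !nzchar(s)])
    cnv_stop(sprintf("invalid CNV state code(s): %s",
                     paste(sQuote(bad), collapse = ", ")))
  }
  signed <- grepl("^[+-]", s)
  dose <- rep(NA_real_, length(s))

  if (any(signed)) {
    sv <- v[signed]
    if (any(!sv %in% c(-2, -1, 1, 2))) {
      cnv_stop(sprintf(
        "signed state codes must be in {-2,-1,+1,+2}; got %s",
        paste(sQuote(unique(s[signed][!sv %in% c(-2, -1, 1, 2)])),
              collapse = ", ")))
    }
    dose[signed] <- sv
  }
  if (any(!signed)) {
    cv <- v[!signed]
    if (any(cv == 2)) {
      cnv_stop("copy number 2 is the neutral state, not a CNV",
               class = "cnvrkit_neutral_state")
    }
    if (any(!cv %in% c(0, 1, 3, 4))) {
      cnv_stop(sprintf(
        "copy-number state codes must be in {0,1,3,4}; got %s",
        paste(sQuote(unique(s[!signed][!cv %in% c(0, 1, 3, 4)])),
              collapse = ", ")))
    }
    map <- c(`0` = -2, `1` = -1, `3` = 1, `4` = 2)
    dose[!signed] <- unname(map[as.character(cv)])
  }
  dose
}

#' Convert a signed dose back to an integer copy number
#'
#' Inverse of the copy-number branch of [normalize_state()]:
#' -2 -> 0, -1 -> 1, +1 -> 3, +2 -> 4.
#'
#' @param dose numeric vector of signed doses.
#' @return integer copy numbers.
#' @export
dose_to_cn <- function(dose) {
  if (any(!dose %in% c(-2, -1, 1, 2))) {
    cnv_stop("dose must be in {-2,-1,1,2}")
  }
  map <- c(`-2` = 0L, `-1` = 1L, `1` = 3L, `2` = 4L)
  unname(map[as.character(dose)])
}
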