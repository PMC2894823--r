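# Covariate-adjusted multiple linear regression of phenotypes on region
# states. The model for each region r is
#   y_i = b0 + b1 * state_ri + c' covariates_i + e_i
# (additive genetic model: the signed-dose state enters as one numeric
# column). Coefficients and standard errors come from solving the normal
# equations by Gaussian elimination with partial pivoting; significance of
# the state term is a two-sided Student t-test with df = n - k (k columns
# including the intercept), and genome-wide significance is declared at
# p < alpha / M where M is the number of regions actually tested.

#' Association-run parameters
#'
#' @param phenotype name of the dependent phenotype column.
#' @param covariates character vector of phenotype columns used for
#'   adjustment (must not contain `phenotype`).
#' @param alpha significance level before Bonferroni correction (default
#'   0.05).
#' @param filters list of [subject_filter()]s restricting the analysis to a
#'   subject subset.
#' @param include_snps logical: combined SNP + CNVR analysis (see
#'   [run_combined_snp_cnvr()]).
#' @return an `association_config` list.
#' @export
association_config <- function(phenotype, covariates = character(),
                               alpha = 0.05, filters = list(),
                               include_snps = FALSE) {
  if (!is_string(phenotype)) cnv_stop("phenotype must be a column name")
  if (phenotype %in% covariates) {
    cnv_stop("the dependent phenotype cannot also be a covariate")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    cnv_stop("alpha must be in (0,1)")
  }
  structure(list(phenotype = phenotype, covariates = covariates,
                 alpha = alpha, filters = filters,
                 include_snps = isTRUE(include_snps)),
            class = "association_config")
}

#' A subject-subset filter
#'
#' Restricts an association run to subjects with particular properties,
#' e.g. only male subjects: `subject_filter("sex", "==", 1)`.
#'
#' @param column phenotype column name.
#' @param op one of `"<", "<=", "==", ">=", ">", "!="`.
#' @param value numeric comparison value.
#' @return a `subject_filter` list.
#' @export
subject_filter <- function(column, op, value) {
  ops <- c("<", "<=", "==", ">=", ">", "!=")
  if (!op %in% ops) {
    cnv_stop(sprintf("filter operator must be one of %s",
                     paste(ops, collapse = " ")))
  }
  if (!is.numeric(value) || length(value) != 1L) {
    cnv_stop("filter value must be a single number")
  }
  structure(list(column = column, op = op, value = value),
            class = "subject_filter")
}

#' Parse a filter expression string
#'
#' Accepts the CLI syntax `"sex==1"`, `"age>=40"` etc.
#'
#' @param text a string `column OP value`.
#' @return a [subject_filter()].
#' @export
parse_filter <- function(text) {
  m <- regmatches(text, regexec("^\\s*([^<>=!]+?)\\s*(<=|>=|==|!=|=|<|>)\\s*(-?[0-9.eE+]+)\\s*$",
                                text))[[1]]
  if (length(m) != 4L) {
    cnv_stop(sprintf("cannot parse filter expression %s (expected e.g. \"sex==1\")",
                     sQuote(text)))
  }
  op <- if (m[3] == "=") "==" else m[3]
  subject_filter(m[2], op, as.numeric(m[4]))
}

#' Apply subject filters to a phenotype table
#'
#' Returns the subjects satisfying all filters; subjects with a missing
#' value in a filtered column are excluded.
#'
#' @param phenos a `phenotype_table`.
#' @param filters list of [subject_filter()]s.
#' @return character vector of subject ids.
#' @export
apply_filters <- function(phenos, filters = list()) {
  keep <- rep(TRUE, nrow(phenos))
  for (f in filters) {
    if (!f$column %in% names(phenos)) {
      cnv_stop(sprintf("filter column %s not in phenotype table",
                       sQuote(f$column)))
    }
    v <- phenos[[f$column]]
    ok <- switch(f$op,
                 "<"  = v <  f$value, "<=" = v <= f$value,
                 "==" = v == f$value, ">=" = v >= f$value,
                 ">"  = v >  f$value, "!=" = v != f$value)
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  phenos$subject_id[keep]
}

#' Build the regression design for one region
#'
#' Columns are `(intercept)`, `state`, then the covariates; rows are the
#' subjects (from `subjects`) with complete data for the response, the
#' state and all covariates (complete-case analysis).
#'
#' @param state_row named numeric vector: the region's state per subject.
#' @param phenos a `phenotype_table`.
#' @param cfg an [association_config()].
#' @param subjects subject ids to consider (already filtered).
#' @return list with `X` (n x k matrix), `y`, `subjects` (rows kept).
#' @export
build_design_matrix <- function(state_row, phenos, cfg, subjects) {
  if (length(subjects) == 0L) cnv_stop("no subjects to analyse")
  miss_cov <- setdiff(c(cfg$phenotype, cfg$covariates), names(phenos))
  if (length(miss_cov)) {
    cnv_stop(sprintf("phenotype column(s) not found: %s",
                     paste(miss_cov, collapse = ", ")))
  }
  rows <- match(subjects, phenos$subject_id)
  if (anyNA(rows)) cnv_stop("subjects missing from the phenotype table")
  y <- phenos[[cfg$phenotype]][rows]
  state <- unname(state_row[subjects])
  covs <- if (length(cfg$covariates)) {
    as.matrix(as.data.frame(phenos[rows, cfg$covariates, drop = FALSE]))
  } else {
    matrix(numeric(0), length(rows), 0)
  }
  cc <- !is.na(y) & !is.na(state)
  if (ncol(covs)) cc <- cc & complete.cases(covs)
  X <- cbind(`(intercept)` = 1, state = state[cc], covs[cc, , drop = FALSE])
  y <- y[cc]
  k <- ncol(X)
  if (length(y) <= k) {
    cnv_stop(sprintf("insufficient observations: n = %d, k = %d",
                     length(y), k), class = "cnvrkit_insufficient_n")
  }
  if (var(X[, "state"]) == 0) {
    cnv_stop("monomorphic state column (no variation between subjects)",
             class = "cnvrkit_monomorphic")
  }
  list(X = X, y = y, subjects = subjects[cc])
}

# Gaussian elimination with partial pivoting on an augmented system
# A | B. Raises a collinearity error naming the offending column when a
# pivot falls below 1e-10 times the largest pivot seen.
gauss_solve <- function(A, B, colnames_ = colnames(A), tol = 1e-10) {
  k <- nrow(A)
  M <- cbind(A, B)
  max_pivot <- 0
  for (j in seq_len(k)) {
    p <- which.max(abs(M[j:k, j])) + j - 1L
    pivot <- abs(M[p, j])
    max_pivot <- max(max_pivot, pivot)
    if (pivot < tol * max_pivot || pivot == 0) {
      cnv_stop(sprintf(
        "collinear or near-singular design: pivot for column %s below tolerance",
        sQuote(colnames_[j] %||% as.character(j))),
        class = "cnvrkit_collinear")
    }
    if (p != j) M[c(j, p), ] <- M[c(p, j), ]
    M[j, ] <- M[j, ] / M[j, j]
    others <- setdiff(seq_len(k), j)
    M[others, ] <- M[others, ] - outer(M[others, j], M[j, ])
  }
  M[, -seq_len(k), drop = FALSE]
}

#' Ordinary least squares via Gaussian elimination
#'
#' Solves the normal equations X'X b = X'y by Gaussian elimination with
#' partial pivoting (Gauss-Jordan on the augmented system, which also
#' yields (X'X)^-1 for the standard errors):
#' `se_j = sqrt(s^2 * [(X'X)^-1]_jj)` with `s^2 = RSS / (n - k)`.
#'
#' @param X n x k design matrix (including the intercept column).
#' @param y response vector of length n.
#' @return list with `betas`, `ses` (named by design columns), `df`
#'   (`n - k`), `rss`, `sigma2` and `fitted`.
#' @examples
#' X <- cbind(`(intercept)` = 1, x = 1:5)
#' fit_ols(X, 2 + 3 * (1:5))
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) cnv_stop("length(y) must equal nrow(X)")
  if (n <= k) cnv_stop(sprintf("insufficient observations: n = %d, k = %d", n, k),
                       class = "cnvrkit_insufficient_n")
  XtX <- crossprod(X)
  sol <- gauss_solve(XtX, cbind(crossprod(X, y), diag(k)),
                     colnames_ = colnames(X))
  betas <- sol[, 1]
  inv <- sol[, -1, drop = FALSE]
  fitted <- drop(X %*% betas)
  rss <- sum((y - fitted)^2)
  df <- n - k
  sigma2 <- rss / df
  ses <- sqrt(pmax(sigma2 * diag(inv), 0))
  names(betas) <- names(ses) <- colnames(X)
  list(betas = betas, ses = ses, df = df, rss = rss, sigma2 = sigma2,
       fitted = fitted)
}

#' Two-sided Student t-test p-value
#'
#' `p = 2 P(T_df >= |beta / se|)`. The degenerate exact-fit case `se = 0`
#' gives p = 0 for a nonzero effect and p = 1 for a zero effect.
#'
#' @param beta effect estimate.
#' @param se standard error (>= 0).
#' @param df residual degrees of freedom (>= 1).
#' @return p-value in [0, 1].
#' @export
t_test_pvalue <- function(beta, se, df) {
  if (any(df < 1)) cnv_stop("df must be >= 1")
  if (any(se < 0)) cnv_stop("se must be >= 0")
  ifelse(se == 0,
         ifelse(beta == 0, 1, 0),
         2 * pt(-abs(beta / se), df))
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / m` for `m` regions tested: a region is genome-wide significant
#' when its p-value falls below this threshold.
#'
#' @param alpha significance level (e.g. 0.05).
#' @param m number of regions tested (>= 1).
#' @return the corrected threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    cnv_stop("m must be a positive integer")
  }
  alpha / m
}

new_assoc_results <- function(df, m, alpha, skipped) {
  rownames(df) <- NULL
  attr(df, "m") <- m
  attr(df, "alpha") <- alpha
  attr(df, "skipped") <- skipped
  class(df) <- c("assoc_results", "data.frame")
  df
}

#' @export
print.assoc_results <- function(x, ...) {
  m <- attr(x, "m"); alpha <- attr(x, "alpha")
  cat(sprintf("Association results: %d region(s) tested", nrow(x)))
  if (!is.null(m) && !is.null(alpha)) {
    cat(sprintf(", Bonferroni threshold %g (alpha %g / M %d), %d significant",
                alpha / m, alpha, m, sum(x$significant, na.rm = TRUE)))
  }
  cat("\n")
  print.data.frame(head(as.data.frame(x), 10), digits = 4, ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk)) {
    cat(sprintf("%d region(s) skipped (see attr(., \"skipped\"))\n", nrow(sk)))
  }
  invisible(x)
}

#' Genome-wide association of phenotypes with CNV region states
#'
#' Fits, for every detected region, the covariate-adjusted linear model
#' `phenotype ~ state + covariates` over the filtered subjects with
#' complete data, and tests the state coefficient with a two-sided Student
#' t-test. The Bonferroni rule uses M = the number of regions actually
#' tested; monomorphic or otherwise untestable regions are listed with
#' their reason in the `skipped` attribute, never silently dropped.
#'
#' @param regions a `cnvr_table` (from [detect_cnvrs()] or
#'   [read_regions_csv()]).
#' @param states region x subject state matrix (from [assign_states()] or
#'   [read_states_csv()]).
#' @param phenos a `phenotype_table`.
#' @param cfg an [association_config()].
#' @return an `assoc_results` data frame sorted by (chromosome, start):
#'   `region_id`, `chromosome`, `start`, `end`, `frequency`, `n`, `beta`,
#'   `se`, `t`, `p`, `df`, `significant`, plus one `beta_<covariate>`
#'   column per covariate. Attributes: `m`, `alpha`, `skipped`.
#' @export
run_gwas <- function(regions, states, phenos, cfg) {
  if (!inherits(cfg, "association_config")) {
    cnv_stop("cfg must be an association_config")
  }
  subjects <- apply_filters(phenos, cfg$filters)
  subjects <- intersect(subjects, colnames(states))
  if (length(subjects) == 0L) {
    cnv_stop("no subjects left after filtering / matching to the state matrix")
  }
  ids <- regions$region_id
  miss <- setdiff(ids, rownames(states))
  if (length(miss)) {
    cnv_stop(sprintf("state matrix lacks region(s): %s",
                     paste(head(miss, 3), collapse = ", ")))
  }
  o <- order(chrom_factor(regions$chromosome), regions$start)
  regions <- regions[o, , drop = FALSE]

  rows <- vector("list", nrow(regions))
  skipped <- list()
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    res <- tryCatch({
      d <- build_design_matrix(states[rid, ], phenos, cfg, subjects)
      fit <- fit_ols(d$X, d$y)
      b <- fit$betas["state"]; s <- fit$ses["state"]
      row <- data.frame(
        region_id = rid,
        chromosome = regions$chromosome[i],
        start = regions$start[i], end = regions$end[i],
        frequency = regions$frequency[i] %||% NA_real_,
        n = length(d$y),
        beta = unname(b), se = unname(s),
        t = unname(ifelse(s == 0, ifelse(b == 0, 0, sign(b) * Inf), b / s)),
        p = unname(t_test_pvalue(b, s, fit$df)),
        df = fit$df,
        stringsAsFactors = FALSE)
      for (cov in cfg$covariates) {
        row[[paste0("beta_", cov)]] <- unname(fit$betas[cov])
      }
      row
    }, cnvrkit_error = function(e) {
      skipped[[length(skipped) + 1L]] <<- data.frame(
        region_id = rid, reason = conditionMessage(e),
        stringsAsFactors = FALSE)
      NULL
    })
    rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    cnv_stop("no testable region (all regions skipped)")
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$significant <- out$p < bonferroni_threshold(cfg$alpha, m)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(region_id = character(), reason = character())
  new_assoc_results(out, m, cfg$alpha, skipped)
}

#' Recompute significance flags at a different alpha
#'
#' Flags are exactly `{p < alpha / M}`; changing alpha rescales them with
#' no refit.
#'
#' @param results an `assoc_results` data frame.
#' @param alpha new significance level (default: the one stored).
#' @return the results with updated flags (attribute `alpha` updated).
#' @export
set_significance <- function(results, alpha = NULL) {
  alpha <- alpha %||% attr(results, "alpha")
  m <- attr(results, "m") %||% nrow(results)
  results$significant <- results$p < bonferroni_threshold(alpha, m)
  attr(results, "alpha") <- alpha
  results
}
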