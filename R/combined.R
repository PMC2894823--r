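# Combined SNP + CNVR association: for each detected region and each
# genotyped SNP inside its span, the cumulative effect of the SNP dose and
# the region state on the phenotype is modeled jointly:
#   y ~ intercept + snp_dose + state + covariates
# with per-term t-tests and a joint 2-df F-test for (snp, state). The
# precise meaning of "cumulative effect" is underdetermined; the joint
# model is this package's design choice (a sum score and sequential
# conditioning are the obvious alternatives) and is documented as such in
# the methods vignette.

#' Combined SNP + CNVR association analysis
#'
#' For every (region, SNP-within-region) pair, fits
#' `phenotype ~ snp_dose + state + covariates` and reports per-term
#' t-tests plus a joint F-test of the two genetic terms against the
#' covariate-only model. When a region's state column is constant over the
#' analysed subjects the model reduces to SNP-only (state term absent, with
#' a warning) and the joint test has 1 df. The Bonferroni rule uses
#' M = the number of (region, SNP) models actually fitted.
#'
#' @inheritParams run_gwas
#' @param genotypes dose matrix from [read_genotype_calls()] (markers x
#'   subjects).
#' @param snp_map SNP map locating each marker (see [read_snp_map()]).
#' @return an `assoc_results` data frame with one row per (region, SNP):
#'   `region_id`, `marker_id`, `chromosome`, `position`, `n`, `beta_snp`,
#'   `se_snp`, `p_snp`, `beta_state`, `se_state`, `p_state`, `f_joint`,
#'   `df1`, `df2`, `p_joint`, `significant`. Regions without genotyped SNPs
#'   are listed in the `skipped` attribute.
#' @export
run_combined_snp_cnvr <- function(regions, states, genotypes, snp_map,
                                  phenos, cfg) {
  if (!inherits(cfg, "association_config")) {
    cnv_stop("cfg must be an association_config")
  }
  subjects <- apply_filters(phenos, cfg$filters)
  subjects <- intersect(subjects, colnames(states))
  subjects <- intersect(subjects, colnames(genotypes))
  if (length(subjects) == 0L) {
    cnv_stop("no subjects shared by phenotypes, states and genotypes")
  }
  o <- order(chrom_factor(regions$chromosome), regions$start)
  regions <- regions[o, , drop = FALSE]
  prow <- match(subjects, phenos$subject_id)
  y_all <- phenos[[cfg$phenotype]][prow]
  covs <- if (length(cfg$covariates)) {
    as.matrix(as.data.frame(phenos[prow, cfg$covariates, drop = FALSE]))
  } else {
    matrix(numeric(0), length(prow), 0)
  }

  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    in_region <- snp_map$chromosome == regions$chromosome[i] &
      snp_map$position >= regions$start[i] &
      snp_map$position <= regions$end[i]
    markers <- intersect(snp_map$marker_id[in_region], rownames(genotypes))
    if (length(markers) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        region_id = rid, reason = "no genotyped SNPs in region",
        stringsAsFactors = FALSE)
      next
    }
    state <- unname(states[rid, subjects])
    region_warned <- FALSE
    for (mk in markers) {
      dose <- unname(genotypes[mk, subjects])
      cc <- !is.na(y_all) & !is.na(dose) & !is.na(state)
      if (ncol(covs)) cc <- cc & complete.cases(covs)
      y <- y_all[cc]
      has_state <- var(state[cc]) > 0
      if (!has_state && !region_warned) {
        warning(sprintf(
          "region %s: state constant over analysed subjects; SNP-only model",
          rid), call. = FALSE)
        region_warned <- TRUE
      }
      if (var(dose[cc]) == 0 && !has_state) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          region_id = rid,
          reason = sprintf("marker %s monomorphic and state constant", mk),
          stringsAsFactors = FALSE)
        next
      }
      gen <- if (has_state) {
        cbind(snp = dose[cc], state = state[cc])
      } else {
        cbind(snp = dose[cc])
      }
      X1 <- cbind(`(intercept)` = 1, gen, covs[cc, , drop = FALSE])
      X0 <- cbind(`(intercept)` = 1, covs[cc, , drop = FALSE])
      res <- tryCatch({
        fit1 <- fit_ols(X1, y)
        fit0 <- fit_ols(X0, y)
        q <- ncol(gen)
        f <- ((fit0$rss - fit1$rss) / q) / fit1$sigma2
        p_joint <- if (fit1$sigma2 == 0) {
          if (fit0$rss > fit1$rss) 0 else 1
        } else {
          pf(f, q, fit1$df, lower.tail = FALSE)
        }
        data.frame(
          region_id = rid, marker_id = mk,
          chromosome = regions$chromosome[i],
          position = snp_map$position[match(mk, snp_map$marker_id)],
          n = length(y),
          beta_snp = unname(fit1$betas["snp"]),
          se_snp = unname(fit1$ses["snp"]),
          p_snp = t_test_pvalue(fit1$betas["snp"], fit1$ses["snp"], fit1$df),
          beta_state = if (has_state) unname(fit1$betas["state"]) else NA_real_,
          se_state = if (has_state) unname(fit1$ses["state"]) else NA_real_,
          p_state = if (has_state) {
            t_test_pvalue(fit1$betas["state"], fit1$ses["state"], fit1$df)
          } else NA_real_,
          f_joint = f, df1 = q, df2 = fit1$df, p_joint = p_joint,
          stringsAsFactors = FALSE)
      }, cnvrkit_error = function(e) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          region_id = rid,
          reason = sprintf("marker %s: %s", mk, conditionMessage(e)),
          stringsAsFactors = FALSE)
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) cnv_stop("no testable (region, SNP) model")
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$significant <- out$p_joint < bonferroni_threshold(cfg$alpha, m)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(region_id = character(), reason = character())
  new_assoc_results(out, m, cfg$alpha, skipped)
}
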