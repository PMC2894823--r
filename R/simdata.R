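# Synthetic CNV study generator. Emulates, at desk scale, the setting the
# detection and association machinery is built for: a cohort genotyped on a
# dense SNP array, per-subject CNV calls from an upstream caller (with
# noisy breakpoints), quantitative phenotypes with covariates, and
# optionally planted CNV regions with a known additive effect so that the
# whole pipeline can be validated end to end. All randomness flows from a
# single seed; identical seeds give byte-identical fixture bundles.

#' A planted CNV region
#'
#' @param chromosome chromosome label.
#' @param start,end planted span (1-based closed bp; snapped to the SNP
#'   grid by the simulator).
#' @param frequency carrier frequency in (0,1): each subject carries the
#'   region's CNV independently with this probability.
#' @param beta additive effect of the signed-dose state on the phenotype
#'   (per dose unit, phenotype SD units when `noise_sd = 1`).
#' @param state_probs named numeric vector of dose probabilities for
#'   carriers, e.g. `c("-1" = 1)` for a pure deletion region.
#' @return a `planted_region` list.
#' @export
planted_region <- function(chromosome, start, end, frequency, beta = 0,
                           state_probs = c("-1" = 1)) {
  if (frequency <= 0 || frequency >= 1) cnv_stop("frequency must be in (0,1)")
  if (end < start) cnv_stop("planted region with end < start")
  if (abs(sum(state_probs) - 1) > 1e-8) {
    cnv_stop("state_probs must sum to 1")
  }
  if (any(!names(state_probs) %in% c("-2", "-1", "1", "2"))) {
    cnv_stop("state_probs names must be doses in {-2,-1,1,2}")
  }
  structure(list(chromosome = as.character(chromosome), start = start,
                 end = end, frequency = frequency, beta = beta,
                 state_probs = state_probs), class = "planted_region")
}

#' Simulation parameters
#'
#' Defaults are sized for desk testing: 500 subjects on 2 chromosomes of
#' 10 Mb with a mean marker spacing of 50 kb (about 200 markers each), one
#' planted 21-SNP deletion region at carrier frequency 0.2 with effect 0.5
#' on an SD-1 phenotype, breakpoint jitter of up to 2 SNPs per side, and a
#' background of 2 random CNVs per subject and chromosome. `cohort_scale =
#' TRUE` switches to a stress preset of the magnitude of a real cohort
#' (1,650 subjects, thousands of CNVs per subject).
#'
#' @param n_subjects number of subjects.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param snp_spacing mean distance between adjacent markers in bp.
#' @param planted_regions list of [planted_region()]s (must not overlap
#'   one another).
#' @param background_rate expected background CNVs per subject per
#'   chromosome (Poisson).
#' @param background_snps integer range of SNPs spanned by a background CNV.
#' @param jitter_snps maximum breakpoint jitter, in SNPs per side, applied
#'   to planted-region carrier calls (models caller noise; this is what
#'   fragments CNVRs and motivates the merge step).
#' @param intercept phenotype intercept.
#' @param age_effect,sex_effect covariate effects (age in years; sex coded
#'   1/2).
#' @param noise_sd residual SD of the phenotype (> 0).
#' @param genotypes logical: also simulate a SNP genotype matrix.
#' @param cohort_scale logical: cohort-scale stress preset.
#' @param seed integer seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 500,
                       chromosomes = c(`1` = 1e7, `2` = 1e7),
                       snp_spacing = 5e4,
                       planted_regions = list(
                         planted_region("1", 4e6, 5e6, frequency = 0.2,
                                        beta = 0.5)),
                       background_rate = 2,
                       background_snps = c(3L, 10L),
                       jitter_snps = 2L,
                       intercept = 25,
                       age_effect = 0.02,
                       sex_effect = 0.5,
                       noise_sd = 1,
                       genotypes = TRUE,
                       cohort_scale = FALSE,
                       seed = 1L) {
  if (isTRUE(cohort_scale)) {
    n_subjects <- 1650
    chromosomes <- setNames(rep(1e8, 4), as.character(1:4))
    snp_spacing <- 1e4
    background_rate <- 1800  # ~7,000 CNVs per subject over 4 chromosomes
  }
  if (noise_sd <= 0) cnv_stop("noise_sd must be > 0")
  if (is.null(names(chromosomes))) cnv_stop("chromosomes must be named")
  # planted regions may not overlap each other
  if (length(planted_regions) > 1) {
    pr <- do.call(rbind, lapply(planted_regions, function(r) {
      data.frame(chromosome = r$chromosome, start = r$start, end = r$end)
    }))
    for (i in seq_len(nrow(pr) - 1)) {
      for (j in (i + 1):nrow(pr)) {
        if (pr$chromosome[i] == pr$chromosome[j] &&
            pr$start[i] <= pr$end[j] && pr$end[i] >= pr$start[j]) {
          cnv_stop("planted regions must not overlap each other")
        }
      }
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 chromosomes = chromosomes, snp_spacing = snp_spacing,
                 planted_regions = planted_regions,
                 background_rate = background_rate,
                 background_snps = as.integer(background_snps),
                 jitter_snps = as.integer(jitter_snps),
                 intercept = intercept, age_effect = age_effect,
                 sex_effect = sex_effect, noise_sd = noise_sd,
                 genotypes = isTRUE(genotypes), seed = as.integer(seed)),
            class = "sim_config")
}

sample_dose <- function(n, probs) {
  doses <- as.numeric(names(probs))
  doses[sample.int(length(doses), n, replace = TRUE, prob = probs)]
}

#' Simulate a complete CNV association study
#'
#' Generates a SNP map (jittered grid at the configured mean spacing),
#' per-subject CNV calls (planted-region carriers drawn i.i.d. at the
#' stated frequency, with breakpoints jittered by up to
#' `cfg$jitter_snps` SNPs per side, plus Poisson background CNVs),
#' a phenotype table (`y = intercept + sum(beta * state) + age and sex
#' effects + Gaussian noise`, with `age` and `sex` columns), an optional
#' genotype dose matrix (per-marker allele frequency uniform on
#' (0.05, 0.5), Hardy-Weinberg doses), and a truth record storing every
#' planted parameter and each subject's true state.
#'
#' @param cfg a [sim_config()].
#' @return list with `snp_map`, `calls` (a `cnv_calls` data frame),
#'   `phenotypes`, `genotypes` (dose matrix or `NULL`), `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cnv_stop("cfg must be a sim_config")
  set.seed(cfg$seed)
  subjects <- sprintf("S%04d", seq_len(cfg$n_subjects))

  # SNP map: regular grid with uniform jitter, per chromosome
  maps <- lapply(names(cfg$chromosomes), function(chrom) {
    len <- cfg$chromosomes[[chrom]]
    n <- max(2L, floor(len / cfg$snp_spacing))
    grid <- seq(cfg$snp_spacing / 2, len - cfg$snp_spacing / 2,
                length.out = n)
    pos <- sort(round(grid + runif(n, -0.3, 0.3) * cfg$snp_spacing))
    pos <- pmax(1, pos)
    pos <- pos + cumsum(c(0, as.numeric(diff(pos) == 0)))  # enforce distinct
    data.frame(marker_id = sprintf("SNP_%s_%05d", chrom, seq_len(n)),
               chromosome = chrom, position = pos,
               stringsAsFactors = FALSE)
  })
  snp_map <- do.call(rbind, maps)
  rownames(snp_map) <- NULL

  calls_list <- list()
  truth_regions <- list()
  true_state <- matrix(0, length(cfg$planted_regions), cfg$n_subjects,
                       dimnames = list(NULL, subjects))

  # planted regions: carriers i.i.d. at the stated frequency, breakpoints
  # jittered on the SNP grid
  for (r in seq_along(cfg$planted_regions)) {
    pl <- cfg$planted_regions[[r]]
    map <- snp_map[snp_map$chromosome == pl$chromosome, , drop = FALSE]
    if (nrow(map) < 4L) cnv_stop("planted region on a chromosome with too few SNPs")
    i0 <- which.min(abs(map$position - pl$start))
    i1 <- which.min(abs(map$position - pl$end))
    if (i1 <= i0) cnv_stop("planted region narrower than the SNP spacing")
    carriers <- which(runif(cfg$n_subjects) < pl$frequency)
    doses <- sample_dose(length(carriers), pl$state_probs)
    true_state[r, carriers] <- doses
    jit <- cfg$jitter_snps
    nc <- length(carriers)
    if (nc) {
      j0 <- pmin(pmax(1L, i0 + sample(-jit:jit, nc, replace = TRUE)),
                 nrow(map) - 1L)
      j1 <- pmax(pmin(nrow(map), i1 + sample(-jit:jit, nc, replace = TRUE)),
                 j0 + 1L)
      calls_list[[length(calls_list) + 1L]] <- data.frame(
        subject_id = subjects[carriers],
        chromosome = pl$chromosome,
        start = map$position[j0], end = map$position[j1],
        state = as.character(dose_to_cn(doses)),
        dose = doses,
        n_snps = j1 - j0 + 1L,
        start_marker = map$marker_id[j0], end_marker = map$marker_id[j1],
        stringsAsFactors = FALSE)
    }
    truth_regions[[r]] <- list(
      chromosome = pl$chromosome,
      start = map$position[i0], end = map$position[i1],
      frequency = pl$frequency, beta = pl$beta,
      n_carriers = length(carriers),
      carriers = subjects[carriers],
      doses = doses)
  }

  # background CNVs: Poisson count per subject and chromosome, random
  # start marker, 3-10 SNP span, random loss/gain
  for (chrom in names(cfg$chromosomes)) {
    map <- snp_map[snp_map$chromosome == chrom, , drop = FALSE]
    n_bg <- rpois(cfg$n_subjects, cfg$background_rate)
    total <- sum(n_bg)
    if (total == 0L) next
    span <- sample(cfg$background_snps[1]:cfg$background_snps[2], total,
                   replace = TRUE)
    j0 <- 1L + floor(runif(total) * pmax(1L, nrow(map) - span))
    j1 <- pmin(nrow(map), j0 + span - 1L)
    dose <- sample(c(-1, 1), total, replace = TRUE)
    calls_list[[length(calls_list) + 1L]] <- data.frame(
      subject_id = rep(subjects, n_bg), chromosome = chrom,
      start = map$position[j0], end = map$position[j1],
      state = as.character(dose_to_cn(dose)), dose = dose,
      n_snps = j1 - j0 + 1L,
      start_marker = map$marker_id[j0], end_marker = map$marker_id[j1],
      stringsAsFactors = FALSE)
  }

  calls <- if (length(calls_list)) {
    do.call(rbind, calls_list)
  } else {
    read_generic_cnv_csv_empty()
  }
  if (nrow(calls)) {
    calls <- calls[order(calls$subject_id, chrom_factor(calls$chromosome),
                         calls$start, calls$end), , drop = FALSE]
  }
  calls <- new_cnv_calls(calls)

  # phenotypes: y = intercept + sum_r beta_r * state_r + covariates + noise
  age <- round(rnorm(cfg$n_subjects, 50, 10), 1)
  sex <- sample(1:2, cfg$n_subjects, replace = TRUE)
  genetic <- if (length(cfg$planted_regions)) {
    colSums(true_state * vapply(cfg$planted_regions, `[[`, numeric(1),
                                "beta"))
  } else {
    rep(0, cfg$n_subjects)
  }
  y <- cfg$intercept + genetic + cfg$age_effect * age +
    cfg$sex_effect * sex + rnorm(cfg$n_subjects, 0, cfg$noise_sd)
  phenotypes <- data.frame(subject_id = subjects, y = y, age = age,
                           sex = sex, stringsAsFactors = FALSE)
  class(phenotypes) <- c("phenotype_table", "data.frame")

  genotypes <- NULL
  if (cfg$genotypes) {
    maf <- runif(nrow(snp_map), 0.05, 0.5)
    genotypes <- matrix(
      rbinom(nrow(snp_map) * cfg$n_subjects, 2L, rep(maf, cfg$n_subjects)),
      nrow = nrow(snp_map),
      dimnames = list(snp_map$marker_id, subjects))
    storage.mode(genotypes) <- "double"
  }

  truth <- list(seed = cfg$seed, n_subjects = cfg$n_subjects,
                subjects = subjects,
                planted = truth_regions,
                true_states = true_state,
                intercept = cfg$intercept,
                age_effect = cfg$age_effect, sex_effect = cfg$sex_effect,
                noise_sd = cfg$noise_sd)
  list(snp_map = snp_map, calls = calls, phenotypes = phenotypes,
       genotypes = genotypes, truth = truth)
}

BUNDLE_FILES <- c(cnv = "cnv_calls.csv",
                  segments = "segment_summary.txt",
                  phenotypes = "phenotypes.csv",
                  genotypes = "genotypes.call",
                  snp_map = "snp_map.csv",
                  truth = "truth.json")

#' Write a simulated dataset as a fixture bundle
#'
#' Writes one file per supported reader: the generic CNV CSV, the
#' segment-summary dialect, the phenotype CSV, the genotype `.call` table
#' (when simulated), the SNP map, and a `truth.json` carrying all planted
#' parameters verbatim. One bundle exercises every import path.
#'
#' @param dataset output of [simulate_dataset()].
#' @param directory output directory (created if missing).
#' @param force overwrite into a non-empty directory.
#' @return named character vector of the written paths.
#' @export
write_fixture_bundle <- function(dataset, directory, force = FALSE) {
  if (dir.exists(directory) &&
      length(list.files(directory, all.files = TRUE, no.. = TRUE)) &&
      !force) {
    cnv_stop(sprintf("directory %s is not empty (use force = TRUE)",
                     directory))
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, BUNDLE_FILES)
  names(paths) <- names(BUNDLE_FILES)
  write_generic_cnv_csv(dataset$calls, paths["cnv"])
  write_segment_summary(dataset$calls, paths["segments"])
  write_phenotypes(dataset$phenotypes, paths["phenotypes"])
  if (!is.null(dataset$genotypes)) {
    write_genotype_calls(dataset$genotypes, paths["genotypes"])
  } else {
    paths <- paths[names(paths) != "genotypes"]
  }
  write_snp_map(dataset$snp_map, paths["snp_map"])
  truth <- dataset$truth
  truth$true_states <- NULL  # matrix restated per planted region
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
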