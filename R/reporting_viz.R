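# Manhattan and region-distribution plots. Every image is accompanied by a
# JSON sidecar (<image>.json) carrying the quantities a reader would
# otherwise have to eyeball: the Bonferroni line height and the M it was
# computed from, and per-point metadata (the file-based stand-in for the
# original interactive click-to-inspect).

#' Plot output specification
#'
#' @param path output image path.
#' @param format `"png"` (default) or `"jpeg"`.
#' @param width,height image size in pixels.
#' @param dpi nominal resolution used to convert pixels to device inches.
#' @return a `plot_spec` list.
#' @export
plot_spec <- function(path, format = c("png", "jpeg"), width = 1200,
                      height = 600, dpi = 96) {
  format <- match.arg(format)
  if (width <= 0 || height <= 0) cnv_stop("plot dimensions must be positive")
  structure(list(path = path, format = format, width = width,
                 height = height, dpi = dpi), class = "plot_spec")
}

# Cumulative x-axis layout: chromosomes concatenated in natural order with
# a fixed gap of 2% of the total plotted span between consecutive ones.
genome_layout <- function(chromosome, start, end) {
  lev <- chrom_levels(chromosome)
  cf <- factor(as.character(chromosome), levels = lev)
  span <- vapply(lev, function(ch) {
    max(end[cf == ch]) - min(start[cf == ch]) + 1
  }, numeric(1))
  lo <- vapply(lev, function(ch) min(start[cf == ch]), numeric(1))
  gap <- 0.02 * sum(span)
  offset <- cumsum(c(0, span[-length(span)] + gap)) - lo
  names(offset) <- lev
  list(levels = lev, offset = offset,
       centers = offset + lo + span / 2)
}

write_sidecar <- function(spec, payload) {
  sidecar <- paste0(spec$path, ".json")
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

save_plot <- function(p, spec) {
  ggplot2::ggsave(spec$path, p, device = spec$format,
                  width = spec$width, height = spec$height,
                  units = "px", dpi = spec$dpi)
  invisible(spec$path)
}

# -log10 display ceiling for p-values that underflow to zero.
MANHATTAN_P_CEILING <- 320

#' Manhattan plot of CNV region associations
#'
#' Plots every region's -log10(p) against its cumulative genomic position
#' (chromosomes concatenated in natural order, alternating colors), with a
#' horizontal Bonferroni line at `-log10(alpha / m)` drawn from the number
#' of tests actually performed. Zero p-values are clipped to a display
#' ceiling of `1e-320` and the caption says so. Catalog-highlighted points
#' (see [annotate_catalog()]) are ringed in yellow; genome-wide significant
#' ones in red.
#'
#' A JSON sidecar `<path>.json` records `alpha`, `m`, the line height, and
#' per-point metadata, so the plotted quantities are machine-checkable.
#'
#' @param results an `assoc_results` data frame (needs `chromosome`,
#'   `start`, `end`, `p`).
#' @param spec a [plot_spec()].
#' @param alpha significance level (default: the one stored in `results`).
#' @param m number of tests for the Bonferroni line (default: stored
#'   attribute, else `nrow(results)`).
#' @return the ggplot object, invisibly (the image and sidecar are written
#'   as a side effect).
#' @export
manhattan_plot <- function(results, spec, alpha = NULL, m = NULL) {
  if (nrow(results) == 0L) cnv_stop("no results to plot")
  alpha <- alpha %||% attr(results, "alpha") %||% 0.05
  m <- m %||% attr(results, "m") %||% nrow(results)
  layout <- genome_layout(results$chromosome, results$start, results$end)

  df <- as.data.frame(results)
  df$chromosome <- factor(as.character(df$chromosome),
                          levels = layout$levels)
  mid <- (df$start + df$end) / 2
  df$x <- mid + layout$offset[as.character(df$chromosome)]
  clipped <- df$p <= 0 | -log10(pmax(df$p, 0)) > MANHATTAN_P_CEILING
  df$logp <- ifelse(clipped, MANHATTAN_P_CEILING, -log10(df$p))
  line_y <- -log10(bonferroni_threshold(alpha, m))

  # alternate two hues so adjacent chromosomes always differ
  palette <- rep(c("#2c7fb8", "#7fcdbb"),
                 length.out = length(layout$levels))
  caption <- if (any(clipped)) {
    sprintf("%d p-value(s) clipped to the display ceiling 1e-%d",
            sum(clipped), MANHATTAN_P_CEILING)
  } else {
    NULL
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$logp,
                                        color = .data$chromosome)) +
    ggplot2::geom_point(size = 1.2, show.legend = FALSE)
  if (!is.null(df$known_association) && any(df$known_association)) {
    p <- p + ggplot2::geom_point(
      data = df[df$known_association, , drop = FALSE],
      color = "gold", shape = 1, size = 3, stroke = 1.1,
      show.legend = FALSE)
  }
  if (!is.null(df$significant) && any(df$significant, na.rm = TRUE)) {
    p <- p + ggplot2::geom_point(
      data = df[which(df$significant), , drop = FALSE],
      color = "red", size = 1.6, show.legend = FALSE)
  }
  p <- p +
    ggplot2::geom_hline(yintercept = line_y, linetype = "dashed",
                        color = "red") +
    ggplot2::scale_color_manual(values = palette) +
    ggplot2::scale_x_continuous(breaks = layout$centers,
                                labels = layout$levels) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p)),
                  caption = caption) +
    ggplot2::theme_minimal()
  save_plot(p, spec)
  write_sidecar(spec, list(
    type = "manhattan", alpha = alpha, m = m,
    bonferroni_p = alpha / m, line_y = line_y,
    n_points = nrow(df), n_clipped = sum(clipped),
    points = df[, intersect(c("region_id", "chromosome", "start", "end",
                              "p", "significant", "known_association"),
                            names(df))]))
  invisible(p)
}

#' Per-chromosome distribution of detected CNV regions
#'
#' One horizontal track per chromosome, each detected region drawn as a
#' segment at its genomic span. Chromosomes without regions still get an
#' (empty) track when listed in `chromosomes`.
#'
#' @param regions a `sub_cnvr_table` or `cnvr_table` (needs `chromosome`,
#'   `start`, `end`).
#' @param spec a [plot_spec()].
#' @param chromosomes chromosome labels to draw tracks for (default: those
#'   present in `regions`).
#' @return the ggplot object, invisibly.
#' @export
region_distribution_plot <- function(regions, spec, chromosomes = NULL) {
  if (nrow(regions) == 0L) cnv_stop("no regions to plot")
  chromosomes <- chrom_levels(chromosomes %||% regions$chromosome)
  df <- as.data.frame(regions)[, c("chromosome", "start", "end")]
  df$chromosome <- factor(as.character(df$chromosome),
                          levels = rev(chromosomes))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$chromosome, yend = .data$chromosome),
      linewidth = 3, color = "#2c7fb8") +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = "position [bp]", y = "chromosome") +
    ggplot2::theme_minimal()
  save_plot(p, spec)
  counts <- table(factor(as.character(regions$chromosome),
                         levels = chromosomes))
  write_sidecar(spec, list(
    type = "region_distribution",
    n_regions = nrow(df),
    chromosomes = chromosomes,
    regions_per_chromosome = as.list(setNames(as.integer(counts),
                                              names(counts)))))
  invisible(p)
}

#' Flag results overlapping a known-association catalog
#'
#' A result is flagged when its span overlaps a catalog region by at least
#' 1 bp on the same chromosome (optionally restricted to one trait).
#' Highlighting is pure annotation: betas, p-values and row order are
#' untouched; the flag propagates to the results CSV and to
#' [manhattan_plot()] styling.
#'
#' @param results an `assoc_results` data frame.
#' @param catalog data frame from [read_catalog()].
#' @param trait optional trait name to filter the catalog by.
#' @return the results with a logical `known_association` column.
#' @export
annotate_catalog <- function(results, catalog, trait = NULL) {
  if (!is.null(trait)) {
    catalog <- catalog[catalog$trait == trait, , drop = FALSE]
  }
  flag <- logical(nrow(results))
  if (nrow(catalog)) {
    for (i in seq_len(nrow(results))) {
      flag[i] <- any(catalog$chromosome == results$chromosome[i] &
                     catalog$start <= results$end[i] &
                     catalog$end >= results$start[i])
    }
  }
  results$known_association <- flag
  results
}
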