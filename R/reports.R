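#' Summarize reconstructed resolution per preset and contrast level
#'
#' Mean and SD of the fitted FWHM of the three largest spheres (22, 28,
#' 37 mm) over all scans, one row per (preset, contrast level) -- the
#' conventional resolution summary table.
#'
#' @param fits Fit rows from [runStudy()].
#' @return data.frame with `preset`, `sbr`, `meanFwhm`, `sdFwhm`, `n`.
#' @export
fwhmSummary <- function(fits) {
  large <- fits[fits$label %in% c("37", "28", "22"), ]
  agg <- stats::aggregate(fwhm ~ preset + sbr, data = large,
                   FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                       n = length(x)))
  out <- data.frame(preset = agg$preset, sbr = agg$sbr,
                    meanFwhm = agg$fwhm[, "mean"],
                    sdFwhm = agg$fwhm[, "sd"], n = agg$fwhm[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$sbr, out$preset), ]
}

#' Summarize background SNR per preset
#'
#' Mean and SD of the background SNR pooled over contrast levels and
#' scans (one SNR value per scan x contrast level), one row per preset.
#'
#' @param metrics MetricsTable from [runStudy()].
#' @return data.frame with `preset`, `meanSnr`, `sdSnr`, `n`.
#' @export
snrSummary <- function(metrics) {
  u <- unique(metrics[, c("preset", "sbr", "scan", "snr")])
  agg <- stats::aggregate(snr ~ preset, data = u,
                   FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                       n = length(x)))
  data.frame(preset = agg$preset, meanSnr = agg$snr[, "mean"],
             sdSnr = agg$snr[, "sd"], n = agg$snr[, "n"],
             stringsAsFactors = FALSE)
}

#' Contrast recovery as a function of sphere diameter
#'
#' Mean CRpeak and CRmax over scans for every (preset, contrast level,
#' sphere diameter) -- the data behind the classic recovery-curve figure.
#'
#' @param metrics MetricsTable from [runStudy()].
#' @return Long data.frame with `preset`, `sbr`, `diameterMm`, `metric`
#'   (`"CRpeak"`/`"CRmax"`), `cr`.
#' @export
recoveryCurves <- function(metrics) {
  aggP <- stats::aggregate(crPeak ~ preset + sbr + diameterMm, metrics, mean)
  aggM <- stats::aggregate(crMax ~ preset + sbr + diameterMm, metrics, mean)
  out <- rbind(
    data.frame(aggP[, 1:3], metric = "CRpeak", cr = aggP$crPeak),
    data.frame(aggM[, 1:3], metric = "CRmax", cr = aggM$crMax))
  out[order(out$metric, out$sbr, out$preset, out$diameterMm), ]
}

#' Pairwise tradeoff matrix
#'
#' Applies [classifyTradeoff()] to every requested (A, B) preset pair.
#'
#' @param metrics MetricsTable from [runStudy()].
#' @param pairs Two-column character matrix (or data.frame) of preset
#'   name pairs; default: all ordered pairs.
#' @return data.frame with `methodA`, `methodB`, `crVerdict`,
#'   `snrVerdict`, `crMaxRelDiff` (largest-magnitude small-sphere CRpeak
#'   difference, %), `snrRelDiff` (%), `snrP`.
#' @export
tradeoffMatrix <- function(metrics, pairs = NULL) {
  presets <- unique(metrics$preset)
  if (is.null(pairs)) {
    pairs <- expand.grid(methodA = presets, methodB = presets,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$methodA != pairs$methodB, ]
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("methodA", "methodB")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- metrics[metrics$preset == pairs$methodA[i], ]
    b <- metrics[metrics$preset == pairs$methodB[i], ]
    tc <- classifyTradeoff(a, b)
    worst <- tc$crRelDiff[which.max(abs(tc$crRelDiff))]
    data.frame(methodA = pairs$methodA[i], methodB = pairs$methodB[i],
               crVerdict = tc$crVerdict, snrVerdict = tc$snrVerdict,
               crMaxRelDiff = unname(worst), snrRelDiff = tc$snrRelDiff,
               snrP = tc$snrTest$pValue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the full report bundle for a study
#'
#' Checks that the study grid is complete (every preset x contrast level
#' x scan x sphere cell present) and assembles the resolution summary,
#' SNR summary, recovery curves and tradeoff matrix.
#'
#' @param metrics,fits Outputs of [runStudy()].
#' @param pairs Optional preset pairs for [tradeoffMatrix()].
#' @return List with `fwhm` (may be `NULL` when no fits were run),
#'   `snr`, `recovery`, `tradeoff` data.frames and `flags` (e.g.
#'   single-scan cells where an SD is undefined).
#' @export
buildReports <- function(metrics, fits = NULL, pairs = NULL) {
  cells <- expand.grid(preset = unique(metrics$preset),
                       sbr = unique(metrics$sbr),
                       scan = unique(metrics$scan),
                       label = unique(metrics$label),
                       stringsAsFactors = FALSE)
  have <- paste(metrics$preset, metrics$sbr, metrics$scan, metrics$label)
  want <- paste(cells$preset, cells$sbr, cells$scan, cells$label)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("incomplete study grid; missing cells: ",
         paste(utils::head(missing, 10), collapse = "; "),
         if (length(missing) > 10) " ...")
  flags <- character()
  if (length(unique(metrics$scan)) * length(unique(metrics$sbr)) < 2)
    flags <- c(flags, "single-run study: SD columns are undefined (NA)")
  list(fwhm = if (!is.null(fits)) fwhmSummary(fits) else NULL,
       snr = snrSummary(metrics),
       recovery = recoveryCurves(metrics),
       tradeoff = tradeoffMatrix(metrics, pairs),
       flags = flags)
}

#' Write a report bundle to CSV
#'
#' Writes each table of a [buildReports()] bundle as a deterministic CSV
#' (fixed column order, no row names) so identical inputs yield
#' byte-identical files.
#'
#' @param reports A [buildReports()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeReports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("fwhm", "snr", "recovery", "tradeoff")) {
    tab <- reports[[nm]]
    if (is.null(tab)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Recovery-curve plot
#'
#' CR versus sphere diameter, one panel per contrast level, colored by
#' preset.
#'
#' @param metrics MetricsTable from [runStudy()].
#' @param metric `"CRpeak"` or `"CRmax"`.
#' @return A ggplot object.
#' @export
plotRecoveryCurves <- function(metrics, metric = c("CRpeak", "CRmax")) {
  metric <- match.arg(metric)
  curves <- recoveryCurves(metrics)
  curves <- curves[curves$metric == metric, ]
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = diameterMm, y = cr, color = preset)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~sbr) +
    ggplot2::labs(x = "sphere diameter (mm)", y = metric,
                  color = "reconstruction") +
    ggplot2::theme_bw()
}

#' Tradeoff-matrix plot
#'
#' Tile plot of the CRpeak / SNR verdicts for each method pair.
#'
#' @param tradeoff Output of [tradeoffMatrix()].
#' @return A ggplot object.
#' @export
plotTradeoff <- function(tradeoff) {
  long <- rbind(
    data.frame(tradeoff[, c("methodA", "methodB")], axis = "CRpeak",
               verdict = tradeoff$crVerdict),
    data.frame(tradeoff[, c("methodA", "methodB")], axis = "SNR",
               verdict = tradeoff$snrVerdict))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = methodB, y = methodA, fill = verdict)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::facet_wrap(~axis) +
    ggplot2::scale_fill_manual(values = c(higher = "#2e7d32",
                                          equal = "grey70",
                                          lower = "#c62828")) +
    ggplot2::labs(x = "method B (comparator)", y = "method A") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
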