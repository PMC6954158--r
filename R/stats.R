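#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped (Wilcoxon's original treatment); the exact null distribution is
#' used for n <= 25 without ties, otherwise the tie-corrected normal
#' approximation with continuity correction. If every difference is zero
#' the comparison is degenerate and p = 1 is returned with a flag.
#'
#' @param x,y Equal-length numeric vectors (pairing by position).
#' @return List with `statistic` (V, the positive-rank sum), `pValue`,
#'   `n` (non-zero pairs), `method`, `degenerate` and
#'   `medianDifference` (of `x - y`).
#' @examples
#' wilcoxonPaired(c(5, 6, 7, 8, 9, 11), c(4, 7, 5, 6, 8, 9))
#' @export
wilcoxonPaired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  dnz <- d[d != 0]
  if (!length(dnz)) {
    return(list(statistic = 0, pValue = 1, n = 0L,
                method = "Wilcoxon signed-rank (degenerate: all zero)",
                degenerate = TRUE, medianDifference = 0))
  }
  exact <- length(dnz) <= 25 && !any(duplicated(abs(dnz)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       n = length(dnz),
       method = if (exact) "Wilcoxon signed-rank (exact)"
                else "Wilcoxon signed-rank (normal approx., tie-corrected)",
       degenerate = FALSE, medianDifference = stats::median(d))
}

#' Mann-Whitney U test (two independent samples)
#'
#' Two-sided rank-sum test; exact null distribution for small untied
#' samples, tie-corrected normal approximation otherwise.
#'
#' @param a,b Numeric vectors (each n >= 3 for a meaningful comparison).
#' @return List with `statistic` (U for sample `a`), `pValue`, `n`,
#'   `method`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$pValue  # exact 2/20
#' @export
mannWhitneyU <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- (length(a) + length(b)) <= 12 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       n = length(a) + length(b),
       method = if (exact) "Mann-Whitney U (exact)"
                else "Mann-Whitney U (normal approx., tie-corrected)")
}

## tie-corrected Kruskal-Wallis H for a ranks-by-group split
.kwStatistic <- function(values, g) {
  n <- length(values)
  rk <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, function(r) length(r) * (mean(r) - (n + 1) / 2)^2))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}

#' Kruskal-Wallis test (k independent samples)
#'
#' For total sample sizes up to `exactLimit` the permutation-exact p-value
#' is computed by enumerating every distinct assignment of the pooled
#' observations to the group sizes; above that, the chi-square
#' approximation of [stats::kruskal.test()] is used (both with tie
#' correction).
#'
#' @param groups List of numeric vectors, each non-empty.
#' @param exactLimit Maximum total n for exact enumeration (default 12).
#' @return List with `statistic` (H, tie-corrected), `pValue`, `n`,
#'   `method`.
#' @examples
#' kruskalWallis(list(c(1, 2), c(3, 4), c(9, 10)))
#' @export
kruskalWallis <- function(groups, exactLimit = 12L) {
  if (!length(groups) || any(!vapply(groups, length, integer(1))))
    stop("all groups must be non-empty")
  sizes <- vapply(groups, length, integer(1))
  n <- sum(sizes)
  pooled <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  hObs <- .kwStatistic(pooled, g)

  if (n <= exactLimit) {
    ## enumerate distinct multiset assignments of indices to groups
    perms <- .groupAssignments(n, sizes)
    hs <- vapply(perms, function(assign) .kwStatistic(pooled, assign),
                 numeric(1))
    p <- mean(hs >= hObs - 1e-12)
    return(list(statistic = hObs, pValue = p, n = n,
                method = "Kruskal-Wallis (exact enumeration)"))
  }
  kt <- stats::kruskal.test(pooled, g)
  list(statistic = unname(kt$statistic), pValue = kt$p.value, n = n,
       method = "Kruskal-Wallis (chi-square approx.)")
}

## all distinct ways to split indices 1..n into groups of the given sizes;
## returns a list of factor vectors of length n
.groupAssignments <- function(n, sizes) {
  out <- list()
  recurse <- function(remaining, gi, labels) {
    if (gi == length(sizes)) {
      labels[remaining] <- gi
      out[[length(out) + 1L]] <<- factor(labels, levels = seq_along(sizes))
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (p in picks) {
      labels2 <- labels
      labels2[p] <- gi
      recurse(setdiff(remaining, p), gi + 1L, labels2)
    }
  }
  recurse(seq_len(n), 1L, rep(NA_integer_, n))
  out
}

#' Relative difference in percent
#'
#' `100 * (a - b) / b`, with `b` the comparator (second-named,
#' conventional) method. Note the definition is not antisymmetric:
#' `relativeDifference(a, b) != -relativeDifference(b, a)` in general.
#'
#' @param a,b Numeric; `b` must be non-zero.
#' @return Percent difference of `a` relative to `b`.
#' @export
relativeDifference <- function(a, b) {
  if (any(b == 0)) stop("comparator b must be non-zero")
  100 * (a - b) / b
}

#' Classify the contrast-vs-noise tradeoff between two methods
#'
#' Applies the tradeoff rules used to compare reconstruction settings:
#' the CRpeak verdict is `"higher"` (or `"lower"`) when the mean relative
#' CRpeak difference exceeds 10% in magnitude for at least one of the
#' three small spheres (10, 13, 17 mm) with a consistent sign
#' (conflicting signs above threshold fall back to `"equal"`); the SNR
#' verdict is decided by a paired Wilcoxon signed-rank test at p < 0.05
#' with the sign of the median SNR difference. Pairing is by scan (and
#' contrast level when several are present).
#'
#' @param metricsA,metricsB MetricsTable data.frames (see
#'   [analyzeVolume()]) for methods A and B covering the same scans,
#'   contrast levels and spheres.
#' @param smallSpheres Labels of the small spheres (default
#'   `c("10", "13", "17")`).
#' @param crThreshold Relative-difference threshold in percent
#'   (default 10).
#' @param alpha Significance level for the SNR test (default 0.05).
#' @return List with `crVerdict`, `snrVerdict` (each
#'   `"higher"`/`"equal"`/`"lower"` for A relative to B),
#'   `crRelDiff` (named per-sphere mean relative differences, %),
#'   `snrRelDiff` (mean relative SNR difference, %), `snrTest` (the
#'   [wilcoxonPaired()] result).
#' @export
classifyTradeoff <- function(metricsA, metricsB,
                             smallSpheres = c("10", "13", "17"),
                             crThreshold = 10, alpha = 0.05) {
  need <- c("scan", "sbr", "label", "crPeak", "snr")
  stopifnot(all(need %in% names(metricsA)), all(need %in% names(metricsB)))
  missA <- setdiff(smallSpheres, metricsA$label)
  missB <- setdiff(smallSpheres, metricsB$label)
  if (length(missA) || length(missB))
    stop("missing sphere rows: ",
         paste(unique(c(missA, missB)), collapse = ", "))

  key <- function(df) paste(df$sbr, df$scan, df$label)
  a <- metricsA[metricsA$label %in% smallSpheres, ]
  b <- metricsB[metricsB$label %in% smallSpheres, ]
  b <- b[match(key(a), key(b)), ]
  if (any(is.na(b$crPeak))) stop("metrics tables do not cover the same cells")

  ## per-sphere mean CRpeak over scans x contrast levels, then rel. diff.
  mA <- tapply(a$crPeak, a$label, mean)[smallSpheres]
  mB <- tapply(b$crPeak, b$label, mean)[smallSpheres]
  crRel <- relativeDifference(mA, mB)
  over <- crRel[abs(crRel) > crThreshold]
  crVerdict <- if (!length(over)) "equal"
  else if (all(over > 0)) "higher"
  else if (all(over < 0)) "lower"
  else "equal"

  ## SNR: one value per (sbr, scan)
  snrOf <- function(df) {
    u <- unique(df[, c("sbr", "scan", "snr")])
    u <- u[order(u$sbr, u$scan), ]
    u
  }
  ua <- snrOf(metricsA); ub <- snrOf(metricsB)
  ub <- ub[match(paste(ua$sbr, ua$scan), paste(ub$sbr, ub$scan)), ]
  wt <- wilcoxonPaired(ua$snr, ub$snr)
  snrVerdict <- if (wt$degenerate || wt$pValue >= alpha ||
                    wt$medianDifference == 0) "equal"
  else if (wt$medianDifference > 0) "higher" else "lower"

  list(crVerdict = crVerdict, snrVerdict = snrVerdict,
       crRelDiff = crRel,
       snrRelDiff = mean(relativeDifference(ua$snr, ub$snr)),
       snrTest = wt)
}
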