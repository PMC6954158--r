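test_that("paired Wilcoxon handles the degenerate all-equal case", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- wilcoxonPaired(x, x)
  expect_true(res$degenerate)
  expect_equal(res$pValue, 1)
})

test_that("paired Wilcoxon exact path equals sign-assignment enumeration", {
  cases <- list(
    list(x = c(5.1, 6.2, 7.3, 8.1, 9.4, 11.2),
         y = c(4.0, 7.1, 5.2, 6.3, 8.2, 9.0)),
    list(x = c(1.2, 2.4, 3.1, 4.9, 5.5),
         y = c(2.0, 2.1, 3.45, 3.8, 5.0)),
    list(x = c(10, 12, 9, 14, 11, 13, 8),
         y = c(11, 10, 8.5, 11.8, 10.2, 12.3, 9.1)))
  for (cs in cases) {
    res <- wilcoxonPaired(cs$x, cs$y)
    expect_match(res$method, "exact")
    expect_equal(res$pValue, wilcoxonSignOracle(cs$x, cs$y),
                 tolerance = 1e-12)
    ## symmetry: swapping the samples leaves p unchanged
    expect_equal(wilcoxonPaired(cs$y, cs$x)$pValue, res$pValue,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact path equals split enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mannWhitneyU(a, b)
  expect_equal(res$pValue, 2 / 20)  # two-sided; one-sided is 1/20
  expect_equal(res$pValue, mannWhitneyOracle(a, b), tolerance = 1e-12)
  cases <- list(
    list(a = c(1.1, 3.2, 5.5, 2.2), b = c(4.1, 6.3, 7.7)),
    list(a = c(9, 12, 15), b = c(10, 11, 13, 14, 16)))
  for (cs in cases) {
    res <- mannWhitneyU(cs$a, cs$b)
    expect_match(res$method, "exact")
    expect_equal(res$pValue, mannWhitneyOracle(cs$a, cs$b),
                 tolerance = 1e-12)
  }
  ## identical samples: U at its null mean, p = 1
  res <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(res$statistic), 9 / 2)
  expect_equal(res$pValue, 1)
  expect_error(mannWhitneyU(numeric(0), b), "non-empty")
})

test_that("Kruskal-Wallis H matches the hand rank formula", {
  groups <- list(c(1, 2), c(3, 4), c(9, 10))
  ## ranks 1..6, group mean ranks 1.5, 3.5, 5.5; no ties
  n <- 6
  hHand <- 12 / (n * (n + 1)) *
    (2 * (1.5 - 3.5)^2 + 2 * (3.5 - 3.5)^2 + 2 * (5.5 - 3.5)^2)
  res <- kruskalWallis(groups)
  expect_equal(res$statistic, hHand, tolerance = 1e-12)
  ## and agrees with the asymptotic statistic in base R
  kt <- kruskal.test(unlist(groups), factor(rep(1:3, each = 2)))
  expect_equal(res$statistic, unname(kt$statistic), tolerance = 1e-12)
})

test_that("Kruskal-Wallis exact path equals assignment enumeration", {
  cases <- list(
    list(g = list(c(1.5, 2.2), c(3.1, 4.7), c(0.3, 6.1))),
    list(g = list(c(12, 15, 11), c(13, 14), c(18, 19, 17))))
  for (cs in cases) {
    res <- kruskalWallis(cs$g)
    expect_match(res$method, "exact")
    expect_equal(res$pValue, kruskalWallisOracle(cs$g), tolerance = 1e-12)
  }
  expect_error(kruskalWallis(list(c(1, 2), numeric(0))), "non-empty")
})

test_that("relative difference uses the comparator as denominator", {
  expect_equal(relativeDifference(1.1, 1.0), 10)
  expect_equal(relativeDifference(3, 3), 0)
  ## definition is not antisymmetric
  expect_false(isTRUE(all.equal(relativeDifference(2, 1),
                                -relativeDifference(1, 2))))
  expect_error(relativeDifference(1, 0), "non-zero")
})

## small synthetic MetricsTable builder: identical methods by construction
syntheticMetrics <- function(crShift = 0, snrShift = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(sbr = c("8:1", "4:1", "2:1"), scan = 1:5,
                      label = c("10", "13", "17"),
                      stringsAsFactors = FALSE)
  grid$crPeak <- 0.6 + 0.02 * as.numeric(grid$label == "17") +
    0.01 * grid$scan / 5 + crShift * (grid$label == "10")
  snrTab <- expand.grid(sbr = c("8:1", "4:1", "2:1"), scan = 1:5,
                        stringsAsFactors = FALSE)
  snrTab$snr <- 7 + 0.3 * snrTab$scan + snrShift
  merge(grid, snrTab, by = c("sbr", "scan"))
}

test_that("tradeoff classification is deterministic and covariant", {
  a <- syntheticMetrics()
  expect_equal(classifyTradeoff(a, a)[c("crVerdict", "snrVerdict")],
               list(crVerdict = "equal", snrVerdict = "equal"))
  ## inflating the 10-mm sphere by 15% flips only the CR verdict
  b <- syntheticMetrics()
  b$crPeak[b$label == "10"] <- b$crPeak[b$label == "10"] * 1.15
  tc <- classifyTradeoff(b, a)
  expect_equal(tc$crVerdict, "higher")
  expect_equal(tc$snrVerdict, "equal")
  ## permutation covariance: swapping A and B maps higher to lower
  tc2 <- classifyTradeoff(a, b)
  expect_equal(tc2$crVerdict, "lower")
  ## a consistent SNR shift with no CR change flips only the SNR verdict
  c2 <- syntheticMetrics(snrShift = 3)
  tc3 <- classifyTradeoff(c2, a)
  expect_equal(tc3$crVerdict, "equal")
  expect_equal(tc3$snrVerdict, "higher")
  ## missing spheres are an error
  expect_error(classifyTradeoff(a[a$label != "13", ], a), "missing sphere")
})
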