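test_that("normality gate behaves like Shapiro-Wilk with guarded input", {
  set.seed(1)
  x <- rnorm(100)
  sw <- shapiro.test(x)
  nt <- normalityTest(x)
  expect_equal(nt$W, unname(sw$statistic))
  expect_equal(nt$p, sw$p.value)
  expect_error(normalityTest(rep(3, 10)),
               class = "coroflow_error_degenerate_input")
  expect_error(normalityTest(c(1, 2)),
               class = "coroflow_error_degenerate_input")
  # skewed data are flagged: lognormal n = 200 rejects in nearly all seeds
  rejected <- vapply(1:40, function(s) {
    set.seed(s); normalityTest(rlnorm(200, 0, 0.8))$p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
  # standard-normal samples are usually not flagged
  kept <- vapply(1:40, function(s) {
    set.seed(1000 + s); normalityTest(rnorm(200))$p > 0.05
  }, logical(1))
  expect_gte(mean(kept), 0.90)
})

test_that("rank-sum test reproduces the enumerable toy exactly", {
  st <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_identical(st$U, 0)
  # brute force: all C(6,3) = 20 assignments, two-sided p = 2/20
  expect_identical(st$pExact, 0.10)
  # swapping the groups flips Z, same p
  st2 <- rankSumTest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(st2$Z, -st$Z)
  expect_equal(st2$p, st$p)
  expect_identical(st2$pExact, st$pExact)
  # identical multisets: centred statistic
  st3 <- rankSumTest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(st3$Z, 0)
  expect_equal(st3$p, 1)
})

test_that("rank-sum agrees with wilcox.test as an independent oracle", {
  set.seed(7)
  for (k in 1:20) {
    x <- round(rnorm(8, 0, 10), 3)
    y <- round(rnorm(6, 2, 10), 3)   # continuous draws: no ties
    st <- rankSumTest(x, y)
    wExact <- wilcox.test(x, y, exact = TRUE)
    expect_equal(st$U, unname(wExact$statistic))
    wNorm <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(st$p, wNorm$p.value, tolerance = 1e-10)
  }
  # tie-corrected variance path against wilcox.test on tied data
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 4, 5, 5, 6)
  st <- rankSumTest(x, y)
  w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(st$p, w$p.value, tolerance = 1e-10)
})

test_that("rank-based p-values are invariant under monotone transforms", {
  set.seed(11)
  x <- rlnorm(12); y <- rlnorm(15, 0.4)
  st <- rankSumTest(x, y)
  for (f in list(log, sqrt, function(v) v^3)) {
    expect_equal(rankSumTest(f(x), f(y))$p, st$p)
  }
  g <- list(rlnorm(6), rlnorm(7, 0.3), rlnorm(5, 0.6))
  h0 <- kruskalWallisTest(g)$statistic
  expect_equal(kruskalWallisTest(lapply(g, log))$statistic, h0)
})

test_that("Kruskal-Wallis H matches kruskal.test and the exact enumeration", {
  g <- list(c(2.1, 4.8, 3.3, 6.1), c(5.0, 7.2, 6.6, 4.4),
            c(9.1, 8.0, 7.7, 10.2))
  kw <- kruskalWallisTest(g)
  ref <- kruskal.test(g)
  expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kw$p, ref$p.value, tolerance = 1e-12)

  # brute-force permutation oracle over all 34650 arrangements of the
  # pooled ranks into groups of 4/4/4
  pooled <- rank(unlist(g))
  N <- 12L
  hOf <- function(r1, r2, r3)
    12 / (N * (N + 1)) * (sum(r1)^2 / 4 + sum(r2)^2 / 4 + sum(r3)^2 / 4) -
      3 * (N + 1)
  idx1 <- utils::combn(12L, 4L)
  hAll <- numeric(0)
  for (c1 in seq_len(ncol(idx1))) {
    g1 <- idx1[, c1]
    rest <- setdiff(1:12, g1)
    idx2 <- utils::combn(rest, 4L)
    for (c2 in seq_len(ncol(idx2))) {
      g2 <- idx2[, c2]
      g3 <- setdiff(rest, g2)
      hAll <- c(hAll, hOf(pooled[g1], pooled[g2], pooled[g3]))
    }
  }
  expect_identical(length(hAll), 34650L)
  pExact <- mean(hAll >= kw$statistic - 1e-12)
  # the chi-square approximation should sit close to the exact tail
  expect_lt(abs(kw$p - pExact), 0.03)
})

test_that("Kruskal-Wallis guards degenerate calls", {
  expect_error(kruskalWallisTest(list(1:3, 4:6)),
               class = "coroflow_error_degenerate_input")
  expect_error(kruskalWallisTest(list(rep(1, 3), rep(1, 4), rep(1, 3))),
               class = "coroflow_error_degenerate_input")
})

test_that("chi-square test matches the Pearson hand computation", {
  st <- chiSquareTest(matrix(c(10, 10, 10, 10), 2))
  expect_equal(st$statistic, 0)
  expect_equal(st$p, 1)

  tab <- matrix(c(20, 5, 5, 20), 2)
  st <- chiSquareTest(tab)
  # all expected counts are 12.5; chi^2 = 4 * 7.5^2 / 12.5 = 18
  expect_equal(st$statistic, 18)
  expect_equal(st$p, pchisq(18, 1, lower.tail = FALSE))

  expect_equal(chiSquareTest(2 * tab)$statistic, 36)
  expect_error(chiSquareTest(matrix(c(0, 0, 3, 4), 2)),
               class = "coroflow_error_degenerate_input")
  expect_error(chiSquareTest(matrix(c(1.5, 2, 3, 4), 2)),
               class = "coroflow_error_degenerate_input")
})

test_that("t and ANOVA behave classically", {
  x <- c(1, 2, 3, 4)
  expect_equal(tTest(x, x)$statistic, 0)
  expect_equal(tTest(x, x)$p, 1)

  # hand recomputation of Welch t on a 4 + 4 toy
  y <- c(2.5, 3.5, 5, 6)
  st <- tTest(x, y)
  se <- sqrt(var(x) / 4 + var(y) / 4)
  expect_equal(st$statistic, (mean(x) - mean(y)) / se, tolerance = 1e-12)

  # two-group ANOVA F equals the square of the pooled-variance t
  set.seed(3)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  f <- onewayAnova(list(a, b))
  tp <- tTest(a, b, varEqual = TRUE)
  expect_equal(f$statistic, tp$statistic^2, tolerance = 1e-10)
  expect_equal(f$p, tp$p, tolerance = 1e-10)
})

test_that("effect sizes follow the pooled-sd definitions", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  expect_equal(effectSize(x, x, "cohen_d"), 0)
  d <- effectSize(x, y, "cohen_d")
  g <- effectSize(x, y, "hedges_g")
  J <- 1 - 3 / (4 * 8 - 1)
  expect_equal(g / d, J, tolerance = 1e-14)
  expect_equal(effectSize(y, x, "cohen_d"), -d)
  expect_equal(d, -1 / sd(x), tolerance = 1e-12)  # pooled sd = sd(x) here
})

test_that("Pearson correlation handles exact linear relations and a hand toy", {
  x <- 1:10
  expect_equal(correlationTest(x, 2 * x + 1)$statistic, 1)
  expect_equal(correlationTest(x, -x)$statistic, -1)
  x5 <- c(1, 3, 4, 6, 8); y5 <- c(2, 3, 5, 5, 9)
  st <- correlationTest(x5, y5)
  rHand <- sum((x5 - mean(x5)) * (y5 - mean(y5))) /
    sqrt(sum((x5 - mean(x5))^2) * sum((y5 - mean(y5))^2))
  expect_equal(st$statistic, rHand, tolerance = 1e-12)
  expect_error(correlationTest(1:2, 2:3),
               class = "coroflow_error_degenerate_input")
})

test_that("subgroup report has the default table shape and flags what it should", {
  co <- generateCohort(sexEffectGenConfig(), seed = 5)
  res <- runCohort(co)$results
  rep <- subgroupReport(res)
  expect_identical(nrow(rep), 11L)
  expect_identical(rep$variable, defaultSubgroupVariables())
  expect_true(all(c("variable", "group_a_summary", "group_b_summary",
                    "test", "statistic", "p", "effect_size",
                    "significant") %in% names(rep)))
  # lognormal CMVR fails the normality gate: rank test + median [IQR]
  expect_true(all(rep$test == "Mann-Whitney U"))
  expect_match(rep$group_a_summary[1], "^male .*\\[")

  # artery row uses Kruskal-Wallis over the three systems
  repA <- subgroupReport(res, "artery")
  expect_identical(repA$test, "Kruskal-Wallis")
  # age row uses correlation
  repAge <- subgroupReport(res, "age")
  expect_identical(repAge$test, "Pearson correlation")

  expect_error(subgroupReport(res, "shoe_size"),
               class = "coroflow_error_unknown_variable")
  # single-group variable: force all smokers
  res2 <- res; res2$smoker <- TRUE
  expect_error(subgroupReport(res2, "smoker"),
               class = "coroflow_error_degenerate_input")
})

test_that("an injected sex effect is detected and does not leak to other rows", {
  # rare comorbidities (valve disease at 5%) may not split a 120-case
  # cohort, so the leak check uses the common covariates
  vars <- c("sex", "smoker", "bmi_gt25", "hypertension", "dyslipidaemia",
            "diabetes", "prior_mi", "lvsd")
  hits <- matrix(NA, 12, length(vars))
  for (s in 1:12) {
    co <- generateCohort(sexEffectGenConfig(nMale = 60L, nFemale = 60L,
                                            cmvrMedian = c(male = 600,
                                                           female = 1100)),
                         seed = 400 + s)
    rep <- subgroupReport(runCohort(co)$results, vars)
    hits[s, ] <- rep$significant
  }
  expect_gte(mean(hits[, 1]), 0.75)          # sex row flagged
  expect_lte(max(colMeans(hits[, -1])), 1 / 3)  # null rows near nominal
})

test_that("Z sign convention: negative when the comparison group runs higher", {
  set.seed(2)
  male <- rlnorm(80, log(680), 0.3)
  female <- rlnorm(80, log(1100), 0.3)
  st <- rankSumTest(male, female)
  expect_lt(st$Z, 0)
  expect_lt(st$effectSize, 0)
})
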