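#' @include AllClasses.R
NULL

## Flat result container for the statistical battery; print method below.
statResult <- function(test, statistic, statisticName, p, effectSize = NA_real_,
                       summaries = character(), extra = list()) {
  structure(c(list(test = test, statistic = statistic,
                   statisticName = statisticName, p = p,
                   effectSize = effectSize, summaries = summaries), extra),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g", x$test, x$statisticName,
              x$statistic, x$p))
  if (!is.na(x$effectSize)) cat(sprintf(", Hedges g = %.3g", x$effectSize))
  cat("\n")
  if (length(x$summaries))
    cat(paste0("  ", names(x$summaries), ": ", x$summaries, collapse = "\n"),
        "\n")
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' @param x numeric sample, 3 <= n <= 5000, non-degenerate
#' @return list with \code{W} and \code{p}
#' @export
normalityTest <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000)
    cfStop("coroflow_error_degenerate_input",
           "Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    cfStop("coroflow_error_degenerate_input",
           "sample is constant; normality is undefined")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

## all C(n, nx) allocations of pooled ranks to the first group; U for each
exactRankSumU <- function(r, nx) {
  combs <- utils::combn(length(r), nx)
  colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U counts pairs where the first sample exceeds the second (ties count
#' half). The two-tailed p uses the normal approximation with tie-corrected
#' variance and (by default) a continuity correction; Z is signed so that a
#' negative value means the second group tends larger. For pooled sizes of
#' at most \code{exactLimit} the exact permutation p (twice the smaller tail
#' of the exact U distribution, capped at 1) is also computed and returned
#' alongside.
#'
#' @param x,y numeric samples (first = reference group)
#' @param continuity apply the 0.5 continuity correction
#' @param exactLimit maximum pooled size for exact enumeration
#' @return a \code{StatResult} with fields \code{U}, \code{Z}, \code{p},
#'   \code{pExact} (NA when not enumerated)
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$pExact  # 0.10
#' @export
rankSumTest <- function(x, y, continuity = TRUE, exactLimit = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1)
    cfStop("coroflow_error_degenerate_input", "both samples must be non-empty")
  N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0)
    cfStop("coroflow_error_degenerate_input",
           "all pooled values tied; rank test is undefined")
  dev <- U - mu
  cc <- if (continuity) sign(dev) * min(0.5, abs(dev)) else 0
  Z <- (dev - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(Z)))
  pExact <- NA_real_
  if (N <= exactLimit) {
    Uall <- exactRankSumU(r, nx)
    pExact <- min(1, 2 * min(mean(Uall <= U), mean(Uall >= U)))
  }
  statResult("Mann-Whitney U", Z, "Z", p,
             effectSize = tryCatch(effectSize(x, y, "hedges_g"),
                                   coroflow_error = function(e) NA_real_),
             extra = list(U = U, Z = Z, pExact = pExact, nx = nx, ny = ny))
}

#' Kruskal-Wallis test (tie-corrected H)
#'
#' @param groups list of at least three non-empty numeric samples
#' @return a \code{StatResult} with H, degrees of freedom and chi-square p
#' @export
kruskalWallisTest <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    cfStop("coroflow_error_degenerate_input",
           "need at least three groups; use rankSumTest for two")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) < 1))
    cfStop("coroflow_error_degenerate_input", "all groups must be non-empty")
  pooled <- unlist(groups)
  if (stats::sd(pooled) == 0)
    cfStop("coroflow_error_degenerate_input",
           "all values identical; ranks are degenerate")
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  Rj <- tapply(r, idx, sum)
  nj <- tapply(r, idx, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  df <- length(groups) - 1
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  statResult("Kruskal-Wallis", H, "H", p, extra = list(H = H, df = df))
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic \eqn{\sum (O - E)^2 / E} without continuity
#' correction.
#'
#' @param tab matrix of non-negative integer counts
#' @return a \code{StatResult} with chi-square statistic, df and p
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    cfStop("coroflow_error_degenerate_input",
           "counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    cfStop("coroflow_error_degenerate_input", "zero marginal in table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  statResult("Pearson chi-square", unname(ct$statistic), "X2", ct$p.value,
             extra = list(df = unname(ct$parameter)))
}

#' Two-sample t test (Welch by default)
#'
#' @param x,y numeric samples with at least two values each
#' @param varEqual use the pooled-variance variant
#' @return a \code{StatResult} with t, df, p and Hedges' g
#' @export
tTest <- function(x, y, varEqual = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    cfStop("coroflow_error_degenerate_input", "need n >= 2 per group")
  tt <- stats::t.test(x, y, var.equal = varEqual)
  statResult(if (varEqual) "t (pooled)" else "t (Welch)",
             unname(tt$statistic), "t", tt$p.value,
             effectSize = effectSize(x, y, "hedges_g"),
             extra = list(t = unname(tt$statistic),
                          df = unname(tt$parameter)))
}

#' One-way ANOVA
#'
#' Classic fixed-effects one-way F test (equal-variance); for two groups the
#' F statistic equals the square of the pooled-variance t.
#'
#' @param groups list of numeric samples, n >= 2 each
#' @return a \code{StatResult} with F, dfs and p
#' @export
onewayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    cfStop("coroflow_error_degenerate_input", "need at least two groups")
  if (any(vapply(groups, length, 1L) < 2))
    cfStop("coroflow_error_degenerate_input", "need n >= 2 per group")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  statResult("one-way ANOVA", unname(ow$statistic), "F", ow$p.value,
             extra = list(df1 = unname(ow$parameter[1]),
                          df2 = unname(ow$parameter[2])))
}

#' Standardised mean difference between two samples
#'
#' Cohen's d uses the pooled standard deviation; Hedges' g multiplies d by
#' the small-sample correction \eqn{J = 1 - 3 / (4\,df - 1)} with
#' \eqn{df = n_x + n_y - 2}.
#'
#' @param x,y numeric samples, n >= 2 each
#' @param kind "cohen_d" or "hedges_g"
#' @return the effect size (sign follows mean(x) - mean(y))
#' @export
effectSize <- function(x, y, kind = c("hedges_g", "cohen_d")) {
  kind <- match.arg(kind)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    cfStop("coroflow_error_degenerate_input", "need n >= 2 per group")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0)
    cfStop("coroflow_error_degenerate_input", "zero pooled variance")
  d <- (mean(x) - mean(y)) / sp
  if (kind == "cohen_d") return(d)
  df <- nx + ny - 2
  d * (1 - 3 / (4 * df - 1))
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite values
#' @return a \code{StatResult} with r and p
#' @export
correlationTest <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    cfStop("coroflow_error_degenerate_input", "need at least 3 finite pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  statResult("Pearson correlation", unname(ct$estimate), "r", ct$p.value,
             extra = list(r = unname(ct$estimate), n = length(x)))
}

#' Default subgroup variables for comparison reports
#'
#' The eleven binary demographic/comorbidity variables of the emulated
#' subgroup table; "artery" (three-level) and "age" (continuous) can be
#' requested in addition.
#'
#' @return character vector of variable names
#' @export
defaultSubgroupVariables <- function() {
  c("sex", "ethnicity", "smoker", "bmi_gt25", "hypertension",
    "dyslipidaemia", "diabetes", "lung_disease", "valve_disease",
    "prior_mi", "lvsd")
}

## reference level first; Z < 0 then means the comparison group tends larger
subgroupGroups <- function(results, variable) {
  switch(variable,
    sex = list(a = results[results$sex == "male", ],
               b = results[results$sex == "female", ],
               la = "male", lb = "female"),
    ethnicity = list(a = results[results$caucasian, ],
                     b = results[!results$caucasian, ],
                     la = "white_caucasian", lb = "black_asian"),
    origin = list(a = results[results$artery != "RCA", ],
                  b = results[results$artery == "RCA", ],
                  la = "left", lb = "right"),
    {
      if (!variable %in% names(results))
        cfStop("coroflow_error_unknown_variable",
               sprintf("unknown variable '%s'", variable))
      list(a = results[!results[[variable]], ],
           b = results[results[[variable]], ], la = "no", lb = "yes")
    })
}

summariseGroup <- function(x, normal) {
  if (normal)
    sprintf("%.3g +/- %.3g", mean(x), stats::sd(x))
  else
    sprintf("%.3g [%.3g-%.3g]", stats::median(x),
            stats::quantile(x, 0.25, names = FALSE),
            stats::quantile(x, 0.75, names = FALSE))
}

normalityGate <- function(xs, alpha = 0.05) {
  ok <- vapply(xs, function(x) {
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) return(FALSE)
    normalityTest(x)$p >= alpha
  }, logical(1))
  all(ok)
}

#' Subgroup comparison report
#'
#' One row per requested variable comparing the outcome between subgroups of
#' the included cases. Binary variables are gated by Shapiro-Wilk on each
#' group: when normality is not rejected the groups are summarised as mean
#' +/- sd and compared with Welch's t, otherwise as median [IQR] with the
#' Mann-Whitney U test. "artery" compares the three systems LAD+Dx, LCx+OM
#' and RCA with Kruskal-Wallis (left-main cases are not assignable to one
#' system and are omitted from that row); "origin" compares left vs right
#' coronary cases; continuous variables ("age") use Pearson correlation.
#' Significance is flagged at the two-tailed alpha, with no multiplicity
#' correction across rows (each row is a nominal-level test).
#'
#' @param results data.frame of processed cases (rows with status
#'   "included" are used; other rows are dropped)
#' @param variables variable names; see
#'   \code{\link{defaultSubgroupVariables}}
#' @param outcome outcome column, default hyperaemic CMVR
#' @param alpha two-tailed significance threshold
#' @return data.frame with columns variable, group_a_summary,
#'   group_b_summary, test, statistic, p, effect_size, significant
#' @export
subgroupReport <- function(results, variables = defaultSubgroupVariables(),
                           outcome = "cmvr_hyper_wu", alpha = 0.05) {
  if (!outcome %in% names(results))
    cfStop("coroflow_error_unknown_variable",
           sprintf("unknown outcome column '%s'", outcome))
  if ("status" %in% names(results))
    results <- results[results$status == "included", , drop = FALSE]
  if (!nrow(results))
    cfStop("coroflow_error_degenerate_input", "no included cases")
  rows <- lapply(variables, function(v)
    subgroupRow(results, v, outcome, alpha))
  do.call(rbind, rows)
}

subgroupRow <- function(results, variable, outcome, alpha) {
  row <- function(ga, gb, test, stat, p, es = NA_real_)
    data.frame(variable = variable, group_a_summary = ga,
               group_b_summary = gb, test = test, statistic = stat,
               p = p, effect_size = es, significant = p < alpha,
               stringsAsFactors = FALSE)

  if (variable == "age") {
    ct <- correlationTest(results$age, results[[outcome]])
    return(row(sprintf("n=%d", ct$n), "", ct$test, ct$statistic, ct$p))
  }
  if (variable == "artery") {
    sys <- ifelse(results$artery %in% c("LAD", "Dx"), "LAD+Dx",
           ifelse(results$artery %in% c("LCx", "OM"), "LCx+OM",
           ifelse(results$artery == "RCA", "RCA", NA)))
    keep <- !is.na(sys)
    groups <- split(results[[outcome]][keep], sys[keep])
    if (length(groups) < 3 || any(vapply(groups, length, 1L) < 1))
      cfStop("coroflow_error_degenerate_input",
             "artery comparison needs cases in all three systems")
    kw <- kruskalWallisTest(groups[c("LAD+Dx", "LCx+OM", "RCA")])
    summ <- vapply(groups[c("LAD+Dx", "LCx+OM", "RCA")],
                   summariseGroup, character(1), normal = FALSE)
    return(row(paste(names(summ)[1], summ[1]),
               paste(names(summ)[-1], summ[-1], collapse = "; "),
               kw$test, kw$statistic, kw$p))
  }
  gr <- subgroupGroups(results, variable)
  xa <- gr$a[[outcome]]; xb <- gr$b[[outcome]]
  if (length(xa) < 2 || length(xb) < 2)
    cfStop("coroflow_error_degenerate_input",
           sprintf("variable '%s' does not split the cohort", variable))
  normal <- normalityGate(list(xa, xb))
  if (normal) {
    st <- tTest(xa, xb)
  } else {
    st <- rankSumTest(xa, xb)
  }
  row(paste(gr$la, summariseGroup(xa, normal)),
      paste(gr$lb, summariseGroup(xb, normal)),
      st$test, st$statistic, st$p, st$effectSize)
}
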