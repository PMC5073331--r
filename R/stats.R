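#' Jarque-Bera normality test
#'
#' Moment-based normality screen: `JB = n/6 * (S^2 + K^2/4)` with sample
#' skewness `S` and excess kurtosis `K` (population-moment estimators), and
#' a p-value from the chi-squared reference with 2 degrees of freedom.  The
#' chi-squared approximation is asymptotic and anti-conservative for small
#' n; here the test is used only as a screen to justify rank-based group
#' comparisons, not for inference.
#'
#' @param x numeric vector, `n >= 4`.
#' @return list with `statistic`, `p_value`, `skewness`, `kurtosis`, `n`;
#'   all `NA` when `n < 4`; errors on a zero-variance sample.
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4)
    return(list(statistic = NA_real_, p_value = NA_real_,
                skewness = NA_real_, kurtosis = NA_real_, n = n))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance sample: normality test undefined")
  S <- mean((x - m)^3) / m2^1.5
  K <- mean((x - m)^4) / m2^2 - 3
  jb <- n / 6 * (S^2 + K^2 / 4)
  list(statistic = jb, p_value = pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K, n = n)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison of two independent groups with midrank
#' handling of ties.  The p-value is exact (by enumeration of rank
#' assignments) when the combined sample size is at most `exact_max` and no
#' ties are present, and uses the normal approximation with tie and
#' continuity corrections otherwise.
#'
#' @param a,b numeric vectors (NA dropped), each with at least 2 values.
#' @param alternative passed to the underlying test (default two-sided).
#' @param exact_max largest combined n for which the exact null
#'   distribution is used.
#' @return list with `U` (the Mann-Whitney U of group `a`), `p_value`,
#'   `n_a`, `n_b`, `exact`.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided", exact_max = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 non-missing values")
  ties <- any(duplicated(c(a, b)))
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p_value = 1,
                n_a = length(a), n_b = length(b), exact = FALSE))
  use_exact <- !ties && (length(a) + length(b)) <= exact_max
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b), exact = use_exact)
}

#' False-discovery-rate adjustment with a no-increase cap
#'
#' Benjamini-Yekutieli step-up adjustment by default, which controls the
#' FDR under arbitrary dependence between the p-values of one family;
#' Benjamini-Hochberg is available for independent or positively dependent
#' families.  The adjusted values are explicitly capped from below by the
#' raw p-values, so correction can never increase significance.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BY"` (default) or `"BH"`.
#' @return adjusted p-values, same length and order as the input.
#' @export
fdr_adjust <- function(pvals, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  pmax(p.adjust(pvals, method = method), pvals, na.rm = FALSE)
}

#' Two-condition comparison of a metrics table, per age
#'
#' For every metric and every DIV: Mann-Whitney test between the two
#' conditions, Jarque-Bera normality screen per group, FDR adjustment of
#' the p-values within the DIV's metric family (families are strictly
#' partitioned by DIV), and significance stars at adjusted p < `alpha`.
#' A metric is excluded from a DIV's family (with a warning) when more than
#' half of either group's cultures are missing it.
#'
#' @param metrics data.frame with columns `culture`, `condition`, `div` and
#'   one numeric column per metric.
#' @param metric_cols character vector of metric columns; defaults to all
#'   numeric columns other than the key columns.
#' @param conditions length-2 character vector; differences are reported as
#'   `conditions[2]` relative to `conditions[1]`.
#' @param alpha significance level on the adjusted p-values.
#' @param method FDR method, see [fdr_adjust()].
#'
#' @return data.frame of class `group_comparison` with one row per
#'   metric x DIV: group sizes, medians and means, `U`, `p_raw`, `p_adj`,
#'   `direction` (+1 when `conditions[2]` has the larger median),
#'   `significant`, `stars`, and per-group normality p-values.
#' @export
compare_study <- function(metrics, metric_cols = NULL,
                          conditions = c("control", "deficient"),
                          alpha = 0.05, method = "BY") {
  stopifnot(all(c("culture", "condition", "div") %in% names(metrics)),
            length(conditions) == 2)
  if (!all(conditions %in% metrics$condition))
    stop("both conditions must be present in the metrics table")
  if (is.null(metric_cols)) {
    ## n_bursts duplicates burst_rate up to the duration factor
    metric_cols <- setdiff(names(metrics),
                           c("culture", "condition", "div", "n_bursts"))
    metric_cols <- metric_cols[vapply(metrics[metric_cols], is.numeric,
                                      logical(1))]
  }
  divs <- sort(unique(metrics$div))
  rows <- list()
  for (div in divs) {
    sub <- metrics[metrics$div == div, , drop = FALSE]
    fam <- list()
    for (mc in metric_cols) {
      g1 <- sub[[mc]][sub$condition == conditions[1]]
      g2 <- sub[[mc]][sub$condition == conditions[2]]
      if (length(g1) < 2 || length(g2) < 2)
        stop("both conditions need >= 2 cultures at DIV ", div)
      if (all(is.na(c(g1, g2)))) next    # metric not computed at this DIV
      if (mean(is.na(g1)) > 0.5 || mean(is.na(g2)) > 0.5) {
        warning("metric ", mc, " missing for more than half of a group ",
                "at DIV ", div, "; excluded from this family")
        next
      }
      mw <- mann_whitney(g1, g2)
      jb1 <- tryCatch(jarque_bera(g1)$p_value, error = function(e) NA_real_)
      jb2 <- tryCatch(jarque_bera(g2)$p_value, error = function(e) NA_real_)
      med1 <- median(g1, na.rm = TRUE); med2 <- median(g2, na.rm = TRUE)
      fam[[mc]] <- data.frame(
        metric = mc, div = div, n_1 = mw$n_a, n_2 = mw$n_b,
        median_1 = med1, median_2 = med2,
        mean_1 = mean(g1, na.rm = TRUE), mean_2 = mean(g2, na.rm = TRUE),
        U = mw$U, p_raw = mw$p_value, p_adj = NA_real_,
        direction = sign(med2 - med1),
        normality_p_1 = jb1, normality_p_2 = jb2,
        stringsAsFactors = FALSE)
    }
    if (length(fam) == 0) next
    famdf <- do.call(rbind, fam)
    famdf$p_adj <- fdr_adjust(famdf$p_raw, method = method)
    rows[[as.character(div)]] <- famdf
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- out$p_adj < alpha
  out$stars <- ifelse(out$p_adj < 0.01, "**",
                      ifelse(out$p_adj < alpha, "*", "ns"))
  attr(out, "conditions") <- conditions
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Fingerprint matrix of a group comparison
#'
#' Condenses a [compare_study()] result into a metric x DIV character
#' matrix: `"ns"`, or the significance stars followed by the direction of
#' the difference of the second condition relative to the first (`+` larger,
#' `-` smaller) -- a compact summary of the developmental phenotype.
#'
#' @param comparison a `group_comparison` data.frame.
#' @return character matrix, metrics in rows, DIVs in columns.
#' @export
fingerprint <- function(comparison) {
  stopifnot(inherits(comparison, "group_comparison"))
  mets <- unique(comparison$metric)
  divs <- sort(unique(comparison$div))
  m <- matrix("ns", nrow = length(mets), ncol = length(divs),
              dimnames = list(mets, paste0("DIV", divs)))
  for (i in seq_len(nrow(comparison))) {
    r <- comparison[i, ]
    m[r$metric, paste0("DIV", r$div)] <-
      if (isTRUE(r$significant))
        paste0(r$stars, if (r$direction >= 0) "+" else "-")
      else "ns"
  }
  m
}
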