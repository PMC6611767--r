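#' Brock nodule-malignancy log-odds
#'
#' The published parsimonious logistic model for the probability that a
#' screening-detected pulmonary nodule is malignant:
#' \deqn{L = 0.0287(age-62) + sex + famHx + emph
#'       - (5.3854((size/10)^{-0.5} - 1.58113883) + type)
#'       + upper - 0.0824(count-4) + spic - 6.7892}
#' The categorical contributions (sex, family history, emphysema, nodule
#' type, upper-lobe location, spiculation) are additive log-odds terms
#' supplied by the caller from the original model's coefficient table;
#' they default to 0 (reference categories). The size spline and age/count
#' centring constants are part of the printed equation: a 62-year-old with
#' a single... with a 4 mm nodule and count 4 sits exactly at the
#' intercept.
#'
#' @param age years.
#' @param sizeMm nodule size in mm (> 0).
#' @param count nodule count.
#' @param sex,familyHistory,emphysema,noduleType,upperLobe,spiculation
#'   additive log-odds contributions of the categorical features.
#' @return Log-odds (vectorised).
#' @export
#' @examples
#' brockLogOdds(62, 4, 4)                # -6.7892 (the intercept)
#' brockProbability(brockLogOdds(62, 4, 4))  # ~0.112 percent
brockLogOdds <- function(age, sizeMm, count = 4, sex = 0, familyHistory = 0,
                         emphysema = 0, noduleType = 0, upperLobe = 0,
                         spiculation = 0) {
  if (any(sizeMm <= 0)) stop("nodule size must be positive")
  0.0287 * (age - 62) + sex + familyHistory + emphysema -
    (5.3854 * ((sizeMm / 10)^(-0.5) - 1.58113883) + noduleType) +
    upperLobe - 0.0824 * (count - 4) + spiculation - 6.7892
}

#' Brock cancer probability (percent)
#'
#' \code{100 * exp(L) / (1 + exp(L))}; strictly increasing in the
#' log-odds.
#'
#' @param logOdds finite log-odds.
#' @return Probability in percent, in \[0, 100\].
#' @export
brockProbability <- function(logOdds) 100 * stats::plogis(logOdds)

.groupComparison <- function(statistic, p, method, sizes) {
  list(statistic = unname(statistic), p_value = unname(p), method = method,
       group_sizes = sizes)
}

#' Kruskal-Wallis H test across groups
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return List with statistic (tie-corrected H), p_value (chi-square,
#'   k - 1 df), method, group_sizes. Identical values across all groups
#'   give H = 0, p = 1.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(.groupComparison(0, 1, "Kruskal-Wallis", lengths(groups)))
  fit <- stats::kruskal.test(groups)
  .groupComparison(fit$statistic, fit$p.value, "Kruskal-Wallis",
                   lengths(groups))
}

#' One-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small tie-free samples (n <= 10 per group),
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @param alternative "greater" (a tends larger) or "less".
#' @return List with statistic (W), p_value, method, group_sizes.
#' @export
wilcoxonOneSided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- length(a) <= 10 && length(b) <= 10 &&
    !anyDuplicated(c(a, b))
  fit <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = alternative, exact = exact, correct = TRUE))
  .groupComparison(fit$statistic, fit$p.value, "one-sided Wilcoxon rank-sum",
                   c(length(a), length(b)))
}

#' One-sided Fisher exact test (hypergeometric tail)
#'
#' The exact tail probability of the 2x2 table at fixed margins, in the
#' stated direction for the top-left cell.
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows = groups,
#'   columns = event / non-event.
#' @param direction "greater" (first group enriched for the event) or
#'   "less".
#' @return List with statistic (the top-left count), p_value, method,
#'   group_sizes. A zero margin gives p = 1.
#' @export
fisherOneSided <- function(tab, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  x <- tab[1, 1]
  K <- tab[1, 1] + tab[2, 1]   # event total
  n1 <- sum(tab[1, ])          # first-group size
  N <- sum(tab)
  if (K == 0 || K == N || n1 == 0 || n1 == N)
    return(.groupComparison(x, 1, "one-sided Fisher exact", rowSums(tab)))
  p <- if (direction == "greater")
    stats::phyper(x - 1, K, N - K, n1, lower.tail = FALSE)
  else stats::phyper(x, K, N - K, n1)
  .groupComparison(x, p, "one-sided Fisher exact", rowSums(tab))
}

#' Chi-square test for trend in proportions
#'
#' Cochran-Armitage trend test over ordered groups (default scores
#' 1..k), two-sided 1-df chi-square p-value.
#'
#' @param events,totals integer vectors per ordered group (>= 3 groups).
#' @param scores ordered group scores.
#' @return List with statistic, p_value, method, group_sizes.
#' @export
chisqTrend <- function(events, totals, scores = seq_along(events)) {
  stopifnot(length(events) >= 3, length(events) == length(totals))
  if (any(totals == 0)) stop("every group needs a non-zero total")
  props <- events / totals
  if (length(unique(props)) == 1L)
    return(.groupComparison(0, 1, "chi-square trend in proportions", totals))
  fit <- suppressWarnings(stats::prop.trend.test(events, totals, scores))
  .groupComparison(fit$statistic, fit$p.value,
                   "chi-square trend in proportions", totals)
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' Studentized-range adjusted p-values for every group pair; groups with a
#' single observation are excluded (with a message).
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with pair, diff, p_adj.
#' @export
tukeyPairwise <- function(groups) {
  stopifnot(length(groups) >= 2)
  small <- lengths(groups) < 2
  if (any(small)) {
    message("excluding group(s) with n = 1: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  stopifnot(length(groups) >= 2)
  df <- data.frame(value = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups)),
                              levels = names(groups)))
  hsd <- stats::TukeyHSD(stats::aov(value ~ g, data = df))$g
  data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
             p_adj = hsd[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}
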