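# Post-hoc procedures not shipped with base R: Games-Howell (pairwise Welch
# comparisons against the studentized range, for heteroscedastic groups) and
# Dunn's rank-based pairwise test with Holm correction (after Kruskal-Wallis).

#' Games-Howell pairwise comparisons
#'
#' Pairwise comparisons for groups with unequal variances: Welch-type
#' standard errors and degrees of freedom, referred to the studentized range
#' distribution.
#'
#' @param values numeric response.
#' @param groups group factor/labels.
#' @return data.frame: `group1`, `group2`, `statistic` (q), `df`, `p_value`.
#' @export
games_howell <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  n <- tapply(values, groups, length)
  combs <- utils::combn(levels(groups), 2L)
  res <- apply(combs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    c(q = unname(q), df = unname(df), p = unname(p))
  })
  data.frame(group1 = combs[1, ], group2 = combs[2, ],
             statistic = res["q", ], df = res["df", ],
             p_value = res["p", ], row.names = NULL)
}

#' Dunn's pairwise rank test
#'
#' Pairwise z statistics on mean ranks with the tie-corrected Kruskal-Wallis
#' variance; p-values are two-sided and adjusted (Holm by default).
#'
#' @param values numeric response.
#' @param groups group factor/labels.
#' @param p_adjust_method passed to [stats::p.adjust()].
#' @return data.frame: `group1`, `group2`, `statistic` (z), `p_value`
#'   (adjusted).
#' @export
dunn_test <- function(values, groups, p_adjust_method = "holm") {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  combs <- utils::combn(levels(groups), 2L)
  z <- apply(combs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    unname((mr[i] - mr[j]) / se)
  })
  p <- p.adjust(2 * stats::pnorm(abs(z), lower.tail = FALSE),
                method = p_adjust_method)
  data.frame(group1 = combs[1, ], group2 = combs[2, ], statistic = z,
             p_value = p, row.names = NULL)
}

#' Significance stars
#'
#' Fixed mapping: `***` for p <= 0.001, `**` for 0.001 < p <= 0.01, `*` for
#' 0.01 < p <= 0.05, else `ns`.
#'
#' @param p p-value(s).
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}
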