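#' Pearson trend of a learning curve
#'
#' Pearson correlation between a run-indexed metric and the chronological
#' run index, with two-sided significance from the Student t distribution:
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' constant series is reported as `r = 0`, `p = 1` with `degenerate =
#' TRUE`, so batch reports never abort on a flat metric.
#'
#' @param value numeric metric values.
#' @param index run indices (default `seq_along(value)`).
#' @return list `r`, `p`, `n`, `slope`, `intercept`, `degenerate`.
#' @export
pearson_trend <- function(value, index = seq_along(value)) {
  keep <- is.finite(value) & is.finite(index)
  value <- value[keep]
  index <- index[keep]
  n <- length(value)
  if (n < 3) stop("need n >= 3 points for a trend")
  if (stats::sd(value) == 0 || stats::sd(index) == 0) {
    return(list(r = 0, p = 1, n = n, slope = 0, intercept = mean(value),
                degenerate = TRUE))
  }
  r <- stats::cor(index, value)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  slope <- r * stats::sd(value) / stats::sd(index)
  list(r = r, p = p, n = n, slope = slope,
       intercept = mean(value) - slope * mean(index), degenerate = FALSE)
}

#' First-vs-last group comparison (Kruskal-Wallis + Tukey-Kramer)
#'
#' Omnibus Kruskal-Wallis test (tie-corrected) across the groups (e.g. the
#' first and last 15 runs of each training period); when the omnibus is
#' significant at `alpha`, Tukey-Kramer pairwise comparisons are computed
#' on the rank means using the studentized-range approximation (infinite
#' degrees of freedom), the rank-based analogue of the standard post-hoc.
#' Set `use_ranks = FALSE` to run the post-hoc on raw values instead
#' (classical Tukey-Kramer on group means with the pooled variance).
#'
#' @param groups named list of numeric vectors.
#' @param alpha omnibus significance level gating the post-hoc (default
#'   0.05).
#' @param use_ranks post-hoc on rank means (default TRUE).
#' @return list `H` (omnibus statistic), `p` (omnibus p), `groups`,
#'   `posthoc` (data.frame `group1`, `group2`, `diff`, `p` or NULL when the
#'   omnibus is not significant).
#' @export
first_last_comparison <- function(groups, alpha = 0.05, use_ranks = TRUE) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (stats::sd(x) == 0) {
    return(list(H = 0, p = 1, groups = names(groups), posthoc = NULL))
  }
  kw <- stats::kruskal.test(x, g)
  posthoc <- NULL
  if (is.finite(kw$p.value) && kw$p.value < alpha) {
    posthoc <- tukey_kramer(x, g, use_ranks = use_ranks)
  }
  list(H = unname(kw$statistic), p = kw$p.value, groups = names(groups),
       posthoc = posthoc)
}

# Internal: Tukey-Kramer pairwise comparisons, on ranks (default) or raw
# values. Rank version: studentized range on rank means with variance
# N(N+1)/12 (tie-corrected), df = Inf. Raw version: pooled within-group
# variance, df = N - k.
tukey_kramer <- function(x, g, use_ranks = TRUE) {
  k <- nlevels(g)
  N <- length(x)
  if (use_ranks) {
    rk <- rank(x)
    centers <- tapply(rk, g, mean)
    ties <- table(rk)
    tiecor <- 1 - sum(ties^3 - ties) / (N^3 - N)
    s2 <- N * (N + 1) / 12 * tiecor
    df <- Inf
  } else {
    centers <- tapply(x, g, mean)
    s2 <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / (N - k)
    df <- N - k
  }
  n_g <- tapply(x, g, length)
  pairs <- utils::combn(levels(g), 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    se <- sqrt(s2 / 2 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    q <- abs(centers[[a]] - centers[[b]]) / se
    res$diff[i] <- centers[[a]] - centers[[b]]
    res$p[i] <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  res
}

#' Section crossing-time comparisons
#'
#' Unpaired two-sided Wilcoxon rank-sum test per section type between two
#' sets of races (e.g. first vs last 15), returning one p value per type.
#' Degenerate samples (all values tied across both groups) are reported as
#' `p = 1` with a flag.
#'
#' @param first,last named lists of numeric vectors, one entry per section
#'   type (`right`, `left`, `headlight`, `noinput`).
#' @return data.frame `section`, `p`, `median_first`, `median_last`,
#'   `degenerate`.
#' @export
section_time_comparison <- function(first, last) {
  types <- union(names(first), names(last))
  if (!length(types)) stop("no section types")
  out <- data.frame(section = types, p = NA_real_,
                    median_first = NA_real_, median_last = NA_real_,
                    degenerate = FALSE)
  for (i in seq_along(types)) {
    a <- first[[types[i]]]
    b <- last[[types[i]]]
    if (is.null(a) || is.null(b) || !length(a) || !length(b)) {
      stop("empty sample for section type ", types[i])
    }
    out$median_first[i] <- stats::median(a)
    out$median_last[i] <- stats::median(b)
    if (stats::sd(c(a, b)) == 0) {
      out$p[i] <- 1
      out$degenerate[i] <- TRUE
    } else {
      out$p[i] <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
    }
  }
  out
}
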