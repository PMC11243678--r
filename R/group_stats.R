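test_report <- function(test, statistic, p, groups = NULL, p_adjusted = NA_real_,
                        extra = list()) {
  structure(c(list(test = test, statistic = as.numeric(statistic),
                   p = as.numeric(p), groups = groups,
                   p_adjusted = p_adjusted), extra),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$test, x$statistic, x$p))
  if (!is.na(x$p_adjusted)) cat(sprintf(", adjusted p = %.4g", x$p_adjusted))
  if (!is.null(x$groups)) cat(sprintf("  [%s]", paste(x$groups, collapse = " vs ")))
  cat("\n")
  invisible(x)
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  pz <- stats::pnorm(z)
  max(seq_len(n) / n - pz, pz - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov normality screen (Lilliefors form)
#'
#' One-sample K-S distance of the sample against a normal with the
#' sample's own mean and standard deviation. Because the reference
#' parameters are estimated, the naive K-S p-value is anti-conservative;
#' the p-value here is calibrated by Monte-Carlo simulation of the null
#' (normal samples of the same size), the Lilliefors construction.
#'
#' @param x numeric sample, `n >= 3`.
#' @param n_sim Monte-Carlo replicates (default 2000).
#' @param seed RNG seed for the calibration draw.
#' @return a `test_report` with the D statistic and Monte-Carlo p.
#' @export
ks_normality <- function(x, n_sim = 2000L, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0)
    return(test_report("Lilliefors K-S (degenerate)", Inf,
                       1 / (n_sim + 1)))
  d_obs <- lilliefors_stat(x)
  n <- length(x)
  d_null <- withr_seed(seed, {
    vapply(seq_len(n_sim), function(i) lilliefors_stat(stats::rnorm(n)),
           numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_sim + 1)
  test_report("Lilliefors K-S", d_obs, p)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  expr
}

mw_u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (two-sample rank test)
#'
#' The U statistic for the first sample (rank-sum form, ties sharing
#' average ranks). Exact mode enumerates all group assignments of the
#' pooled values and reports `P(|U - n_a n_b / 2| >= |observed|)`, valid
#' under ties; otherwise the p-value is the normal approximation with
#' tie correction and continuity correction (via [stats::wilcox.test()]).
#'
#' @param a,b numeric samples.
#' @param exact `TRUE`, `FALSE`, or `NULL` (auto: exact when
#'   `choose(n, n_a) <= 20000`).
#' @return a `test_report` with `u`, the mode used, and p.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  u <- mw_u_stat(a, b)
  na <- length(a); nb <- length(b)
  if (is.null(exact)) exact <- choose(na + nb, na) <= 20000
  if (exact) {
    pool <- c(a, b)
    mu <- na * nb / 2
    dev_obs <- abs(u - mu)
    idx <- utils::combn(na + nb, na)
    devs <- apply(idx, 2, function(ii) abs(mw_u_stat(pool[ii], pool[-ii]) - mu))
    p <- mean(devs >= dev_obs - 1e-9)
    mode <- "exact_permutation"
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    p <- wt$p.value
    mode <- "normal_approx"
  }
  test_report(sprintf("Mann-Whitney U (%s)", mode), u, p,
              extra = list(u = u, mode = mode))
}

kw_h_stat <- function(values, g) {
  # tie-corrected Kruskal-Wallis H, matching stats::kruskal.test
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(as.integer(g))) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

#' Kruskal-Wallis k-sample rank test
#'
#' Tie-corrected H statistic with a chi-squared p-value (df = k - 1) via
#' [stats::kruskal.test()]; exact mode enumerates every assignment of the
#' pooled observations to the group sizes and reports
#' `P(H_perm >= H_obs)`.
#'
#' @param groups named list of numeric samples (>= 2 groups, total
#'   n >= 5 for the chi-squared approximation).
#' @param exact `TRUE`, `FALSE` or `NULL` (auto: exact when the number of
#'   distinct assignments is <= 20000).
#' @return a `test_report`.
#' @export
kruskal_wallis <- function(groups, exact = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  n <- length(values)
  n_assign <- factorial(n) / prod(factorial(sizes))
  if (is.null(exact)) exact <- n_assign <= 20000
  if (length(unique(values)) == 1L)   # all observations tied: no evidence
    return(test_report("Kruskal-Wallis (degenerate)", 0, 1,
                       groups = names(groups),
                       extra = list(mode = "degenerate", df = length(groups) - 1)))
  kt <- stats::kruskal.test(values, g)
  h <- unname(kt$statistic)
  if (exact) {
    h_perm <- kw_perm_stats(values, sizes)
    p <- mean(h_perm >= h - 1e-9)
    mode <- "exact_permutation"
  } else {
    p <- kt$p.value
    mode <- "chi_squared"
  }
  test_report(sprintf("Kruskal-Wallis (%s)", mode), h, p,
              groups = names(groups), extra = list(mode = mode, df = length(groups) - 1))
}

# H over every distinct assignment of pooled values into the group sizes
kw_perm_stats <- function(values, sizes) {
  n <- length(values)
  assignments <- list(list(rest = seq_len(n), groups = list()))
  for (s in sizes[-length(sizes)]) {
    nxt <- list()
    for (st in assignments) {
      picks <- utils::combn(st$rest, s, simplify = FALSE)
      for (p in picks)
        nxt[[length(nxt) + 1L]] <- list(rest = setdiff(st$rest, p),
                                        groups = c(st$groups, list(p)))
    }
    assignments <- nxt
  }
  vapply(assignments, function(st) {
    idx <- c(st$groups, list(st$rest))
    g <- integer(n)
    for (k in seq_along(idx)) g[idx[[k]]] <- k
    kw_h_stat(values, factor(g))
  }, numeric(1))
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' All `k(k-1)/2` pairwise comparisons, each adjusted as
#' `p_adj = min(1, m * p)` (via [stats::p.adjust()]), the post hoc step
#' after a significant Kruskal-Wallis result.
#'
#' @param groups named list of numeric samples.
#' @param exact passed to [mann_whitney_u()].
#' @return list of `test_report`s, one per pair, each carrying the
#'   adjusted p.
#' @export
bonferroni_pairwise <- function(groups, exact = NULL) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2, simplify = FALSE)
  reports <- lapply(pairs, function(pr)
    mann_whitney_u(groups[[pr[1]]], groups[[pr[2]]], exact = exact))
  raw <- vapply(reports, `[[`, numeric(1), "p")
  adj <- stats::p.adjust(raw, method = "bonferroni")
  for (i in seq_along(reports)) {
    reports[[i]]$p_adjusted <- adj[i]
    reports[[i]]$groups <- names(groups)[pairs[[i]]]
  }
  reports
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value by the t
#' approximation (via [stats::cor.test()]). Used to confirm that SAVI
#' and NDVI track each other per zone before SAVI is adopted for the
#' cover analysis.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `test_report` with `r` and p.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  test_report("Spearman rank correlation", unname(ct$estimate), ct$p.value,
              extra = list(r = unname(ct$estimate)))
}
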