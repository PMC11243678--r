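.mk_cache <- new.env(parent = emptyenv())

# exact null pmf of S for a tie-free series of length n, via the
# inversion-number generating function prod_{i=2..n}(1 + x + .. + x^{i-1});
# S = n(n-1)/2 - 2 * inversions
mk_s_distribution <- function(n) {
  key <- sprintf("notie_%d", n)
  if (!is.null(.mk_cache[[key]])) return(.mk_cache[[key]])
  f <- 1
  if (n >= 2) for (i in 2:n) {
    g <- rep(1, i)
    nf <- length(f) + i - 1L
    acc <- numeric(nf)
    for (j in seq_along(g)) acc[j:(j + length(f) - 1L)] <-
        acc[j:(j + length(f) - 1L)] + f
    f <- acc
  }
  S <- n * (n - 1) / 2 - 2 * (seq_along(f) - 1)
  d <- list(S = S, prob = f / sum(f))
  .mk_cache[[key]] <- d
  d
}

# all permutations of 1..n as an (n!) x n matrix, cached
all_perms <- function(n) {
  key <- sprintf("perms_%d", n)
  if (!is.null(.mk_cache[[key]])) return(.mk_cache[[key]])
  p <- if (n == 1L) matrix(1L, 1, 1) else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      rest <- seq_len(n)[-k]
      cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    }))
  }
  .mk_cache[[key]] <- p
  p
}

# Kendall score of y against time order (pairwise sign sum)
mk_score <- function(y) {
  n <- length(y)
  s <- 0L
  for (i in seq_len(n - 1L))
    s <- s + sum(sign(y[(i + 1L):n] - y[i]))
  s
}

# exact permutation null of S for a tied multiset (n <= 7), cached by
# the rank signature of the sorted values
mk_tie_null <- function(y) {
  n <- length(y)
  sig <- paste(tabulate(match(sort(y), unique(sort(y)))), collapse = "_")
  key <- sprintf("tie_%d_%s", n, sig)
  if (!is.null(.mk_cache[[key]])) return(.mk_cache[[key]])
  P <- all_perms(n)
  ys <- sort(y)
  V <- matrix(ys[P], nrow(P), n)
  S <- numeric(nrow(P))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    S <- S + sign(V[, j] - V[, i])
  tb <- table(S)
  d <- list(S = as.numeric(names(tb)), prob = as.numeric(tb) / nrow(P))
  .mk_cache[[key]] <- d
  d
}

#' Mann-Kendall test for monotonic trend
#'
#' Score `S = sum_{i<j} sign(y_j - y_i)` over observations in time order,
#' denominator `D = n(n-1)/2` (the maximum score), `tau = S/D`. The
#' two-sided p-value comes from the exact null distribution of S when
#' n <= 10 and the series has no ties, or by exhaustive permutation
#' enumeration when tied and n <= 7; otherwise from the normal
#' approximation with continuity correction and the tie-corrected
#' variance `[n(n-1)(2n+5) - sum t(t-1)(2t+5)] / 18`. The trend is
#' classed positive when `S > 0` and `p < alpha`, negative when `S < 0`
#' and `p < alpha`, else neutral.
#'
#' @param y observations in time order; `NA`s (cloud gaps) are dropped.
#' @param alpha significance level for the trend class (default 0.05).
#' @param min_n fewer valid observations than this (default 4) yields an
#'   `"insufficient"` result rather than an error, so chronically cloudy
#'   pixels cannot abort a map.
#' @return an object of class `mk_result`: list with `s`, `d`, `tau`,
#'   `p`, `n`, `trend` ("positive"/"negative"/"neutral"/"insufficient"),
#'   `method`.
#' @export
mann_kendall <- function(y, alpha = 0.05, min_n = 4L) {
  y <- as.numeric(y)
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < min_n)
    return(structure(list(s = NA_integer_, d = NA_real_, tau = NA_real_,
                          p = NA_real_, n = n, trend = "insufficient",
                          method = "none"), class = "mk_result"))
  s <- mk_score(y)
  d <- n * (n - 1) / 2
  tau <- s / d
  ties <- anyDuplicated(y) > 0L
  if (!ties && n <= 10L) {
    dist <- mk_s_distribution(n)
    p <- sum(dist$prob[abs(dist$S) >= abs(s)])
    method <- "exact"
  } else if (ties && n <= 7L) {
    dist <- mk_tie_null(y)
    p <- sum(dist$prob[abs(dist$S) >= abs(s) - 1e-9])
    method <- "exact_permutation"
  } else {
    t_sizes <- table(y)
    varS <- (n * (n - 1) * (2 * n + 5) -
             sum(t_sizes * (t_sizes - 1) * (2 * t_sizes + 5))) / 18
    if (varS <= 0) {
      p <- 1
    } else {
      z <- (abs(s) - 1) / sqrt(varS)
      p <- if (s == 0) 1 else min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  trend <- if (p < alpha && s > 0) "positive"
           else if (p < alpha && s < 0) "negative" else "neutral"
  structure(list(s = as.integer(s), d = d, tau = tau, p = p, n = n,
                 trend = trend, method = method), class = "mk_result")
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %s, D = %s, tau = %.4f, p = %.4g (%s), n = %d -> %s\n",
              x$s, x$d, x$tau, x$p, x$method, x$n, x$trend))
  invisible(x)
}

#' Per-pixel Mann-Kendall trend map
#'
#' Aggregates each pixel's monthly series to yearly medians (default) or
#' keeps the monthly series, then runs [mann_kendall()] independently per
#' pixel. Pixels with fewer than `min_n` usable aggregation units are
#' NoData in all outputs.
#'
#' @param stack a `scene_stack` of index values.
#' @param aggregation `"yearly"` (median of valid months per year) or
#'   `"monthly"`.
#' @param alpha significance level (default 0.05).
#' @param min_n minimum series length per pixel.
#' @return list of three aligned `dune_grid`s: `tau`, `p`, and `class`
#'   (+1 positive, -1 negative, 0 neutral, NoData where insufficient).
#' @export
trend_map <- function(stack, aggregation = c("yearly", "monthly"),
                      alpha = 0.05, min_n = 4L) {
  stopifnot(inherits(stack, "scene_stack"))
  aggregation <- match.arg(aggregation)
  if (stack_length(stack) == 0L) stop("empty stack")
  a <- stack_array(stack)
  meta <- stack$grids[[1]]$meta
  if (aggregation == "yearly") {
    yrs <- sort(unique(stack$timestamps$year))
    b <- array(NA_real_, c(meta$rows, meta$cols, length(yrs)))
    for (k in seq_along(yrs)) {
      sel <- stack$timestamps$year == yrs[k]
      slab <- a[, , sel, drop = FALSE]
      b[, , k] <- apply(slab, c(1, 2), function(v)
        if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
    }
    a <- b
  }
  tau <- p <- cls <- matrix(NA_real_, meta$rows, meta$cols)
  for (i in seq_len(meta$rows)) for (j in seq_len(meta$cols)) {
    r <- mann_kendall(a[i, j, ], alpha = alpha, min_n = min_n)
    if (r$trend != "insufficient") {
      tau[i, j] <- r$tau
      p[i, j] <- r$p
      cls[i, j] <- switch(r$trend, positive = 1, negative = -1, neutral = 0)
    }
  }
  list(tau = grid_new(tau, meta = meta),
       p = grid_new(p, meta = meta),
       class = grid_new(cls, meta = meta))
}

#' Summarise a trend map
#'
#' The per-map significance summary: fraction of pixels in each trend
#' class and the median per-pixel p-value (the package's map-level
#' statistics; no single map-level p is defined).
#'
#' @param tm the list returned by [trend_map()].
#' @return data.frame with n_pixels, frac_positive, frac_negative,
#'   frac_neutral, frac_significant, median_p.
#' @export
trend_summary <- function(tm) {
  cls <- grid_values(tm$class)
  n <- length(cls)
  data.frame(n_pixels = n,
             frac_positive = mean(cls == 1),
             frac_negative = mean(cls == -1),
             frac_neutral = mean(cls == 0),
             frac_significant = mean(cls != 0),
             median_p = stats::median(grid_values(tm$p)))
}
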