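# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: scores by explicit double loops, permutation nulls
# by a locally written exhaustive generator.

oracle_mk_s <- function(y) {
  n <- length(y)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    s <- s + sign(y[j] - y[i])
  s
}

# all orderings of v, one row per permutation (recursive, independent of
# the package's generator)
oracle_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1, 1))
  out <- NULL
  for (k in seq_len(n))
    out <- rbind(out, cbind(v[k], oracle_perms(v[-k])))
  out
}

# exact two-sided Mann-Kendall p: share of orderings of the observed
# multiset whose |S| reaches the observed |S|
oracle_mk_exact_p <- function(y) {
  P <- oracle_perms(y)
  s_obs <- abs(oracle_mk_s(y))
  s_all <- apply(P, 1, oracle_mk_s)
  mean(abs(s_all) >= s_obs)
}

# U for group a against b by direct pair counting (ties count half)
oracle_mw_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# exact two-sided MW p over all group assignments of the pooled values
oracle_mw_exact_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  mu <- na * length(b) / 2
  dev_obs <- abs(oracle_mw_u(a, b) - mu)
  devs <- apply(utils::combn(length(pool), na), 2, function(ii)
    abs(oracle_mw_u(pool[ii], pool[-ii]) - mu))
  mean(devs >= dev_obs - 1e-9)
}

# exact KW p: enumerate assignments, H via stats::kruskal.test each time
oracle_kw_exact_p <- function(groups) {
  pool <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  h_obs <- unname(stats::kruskal.test(pool,
    factor(rep(seq_along(sizes), sizes)))$statistic)
  n <- length(pool)
  count <- 0; total <- 0
  for (ii in utils::combn(n, sizes[1], simplify = FALSE)) {
    rest1 <- setdiff(seq_len(n), ii)
    for (jj in utils::combn(rest1, sizes[2], simplify = FALSE)) {
      kk <- setdiff(rest1, jj)
      g <- integer(n); g[ii] <- 1L; g[jj] <- 2L; g[kk] <- 3L
      h <- unname(stats::kruskal.test(pool, factor(g))$statistic)
      total <- total + 1
      if (h >= h_obs - 1e-9) count <- count + 1
    }
  }
  count / total
}

# small aligned grid with optional NoData cells
make_grid <- function(values, meta = NULL) {
  dunedyn::grid_new(as.matrix(values), meta = meta)
}

random_stack <- function(rows, cols, years, seed, na_frac = 0) {
  set.seed(seed)
  months <- expand.grid(month = 1:12, year = years)
  grids <- lapply(seq_len(nrow(months)), function(k) {
    v <- matrix(rnorm(rows * cols), rows, cols)
    if (na_frac > 0) v[runif(rows * cols) < na_frac] <- NA
    dunedyn::grid_new(v)
  })
  dunedyn::assemble_stack(grids = grids, years = months$year,
                          months = months$month)
}
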