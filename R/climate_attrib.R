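#' Gower-center a distance matrix
#'
#' `G = -1/2 J D^2 J` with `J = I - 11'/n` the centering projector: the
#' centered inner-product matrix whose eigen-structure underlies
#' principal coordinates, DistLM and dbRDA. G is symmetric with zero row
#' sums; for Euclidean distances on a data matrix X it equals the
#' centered `X X'`.
#'
#' @param d a symmetric distance matrix (or `dist` object) with zero
#'   diagonal and non-negative entries.
#' @return the centered Gower matrix.
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  n <- nrow(d)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a); gm <- mean(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  g <- (g + t(g)) / 2
  dimnames(g) <- NULL
  g
}

# hat matrix of a model matrix (with intercept prepended)
hat_matrix <- function(x) {
  x <- cbind(1, as.matrix(x))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
    stop(sprintf("design is rank-deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  q <- qr.Q(qr_x)
  tcrossprod(q)
}

# pseudo-F of covariate block X given Gower matrix G (McArdle-Anderson):
# F = [tr(HGH)/q] / [tr((I-H)G(I-H)) / (n-q-1)]
pseudo_f <- function(g, h, q) {
  n <- nrow(g)
  ss_fit <- sum(h * g)            # tr(HG) = tr(HGH), H idempotent symmetric
  ss_tot <- sum(diag(g))
  ss_res <- ss_tot - ss_fit
  f <- (ss_fit / q) / (ss_res / (n - q - 1))
  list(f = f, ss_fit = ss_fit, ss_res = ss_res, ss_tot = ss_tot,
       r2 = ss_fit / ss_tot)
}

adj_r2 <- function(r2, n, q) 1 - (1 - r2) * (n - 1) / (n - q - 1)

#' Distance-based linear model (DistLM)
#'
#' Partitions the variation of a resemblance matrix against climate
#' covariates. Per covariate, the marginal pseudo-F
#' `[tr(HGH)/1] / [tr((I-H)G(I-H))/(n-2)]` (McArdle-Anderson trace form
#' on the Gower-centered matrix) with a permutation p-value obtained by
#' permuting sample identities of the resemblance matrix. Forward
#' step-wise selection adds, at each step, the covariate giving the
#' largest adjusted R-squared, and stops when no addition increases it.
#' With a univariate Euclidean response this pseudo-F reduces exactly to
#' the classical regression F.
#'
#' @param response a numeric matrix of per-sample responses (Euclidean
#'   distances are computed), or a `dist`/square distance matrix.
#' @param covariates data.frame or matrix of covariates (columns named).
#' @param n_perm number of permutations for marginal p-values (>= 99).
#' @param seed RNG seed for the permutations (mandatory for
#'   reproducibility).
#' @return an object of class `distlm`: list with `marginal` (data.frame
#'   covariate, pseudo_f, p_perm, prop_var), `selection` (data.frame
#'   step, covariate, r2, adj_r2), `n`, `total_ss`.
#' @export
distlm <- function(response, covariates, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  g <- response_to_gower(response)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(g)
  if (nrow(x) != n) stop("covariates and response sample counts differ")

  marg <- withr_seed(seed, {
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
    do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
      h <- hat_matrix(x[, j, drop = FALSE])
      obs <- pseudo_f(g, h, 1)
      f_perm <- vapply(perms, function(p) pseudo_f(g[p, p], h, 1)$f,
                       numeric(1))
      data.frame(covariate = colnames(x)[j], pseudo_f = obs$f,
                 p_perm = (1 + sum(f_perm >= obs$f - 1e-12)) / (n_perm + 1),
                 prop_var = obs$r2)
    }))
  })

  # forward selection by adjusted R^2
  remaining <- seq_len(ncol(x)); chosen <- integer(0)
  sel <- data.frame(step = integer(), covariate = character(),
                    r2 = numeric(), adj_r2 = numeric())
  best_adj <- -Inf
  repeat {
    if (length(remaining) == 0L) break
    cand <- vapply(remaining, function(j) {
      h <- hat_matrix(x[, c(chosen, j), drop = FALSE])
      r2 <- pseudo_f(g, h, length(chosen) + 1)$r2
      adj_r2(r2, n, length(chosen) + 1)
    }, numeric(1))
    k <- which.max(cand)
    if (cand[k] <= best_adj) break
    chosen <- c(chosen, remaining[k])
    h <- hat_matrix(x[, chosen, drop = FALSE])
    r2 <- pseudo_f(g, h, length(chosen))$r2
    sel <- rbind(sel, data.frame(step = length(chosen),
                                 covariate = colnames(x)[remaining[k]],
                                 r2 = r2, adj_r2 = cand[k]))
    best_adj <- cand[k]
    remaining <- remaining[-k]
  }
  structure(list(marginal = marg, selection = sel, n = n,
                 total_ss = sum(diag(g))), class = "distlm")
}

response_to_gower <- function(response) {
  if (inherits(response, "dist")) return(gower_center(response))
  response <- as.matrix(response)
  if (nrow(response) == ncol(response) && all(diag(response) == 0) &&
      isTRUE(all.equal(response, t(response), tolerance = 1e-10)))
    return(gower_center(response))
  gower_center(stats::dist(response))
}

#' @export
print.distlm <- function(x, ...) {
  cat(sprintf("DistLM on %d samples (total SS %.4g)\nMarginal tests:\n",
              x$n, x$total_ss))
  print(x$marginal, row.names = FALSE)
  cat("Step-wise selection (adjusted R^2):\n")
  print(x$selection, row.names = FALSE)
  invisible(x)
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' Constrained ordination of the fitted component of the Gower-centered
#' resemblance matrix: eigen-decomposition of `H G H` where H is the hat
#' matrix of the covariates. Axes are sorted by eigenvalue; sample
#' scores are eigenvectors scaled by the square root of their
#' eigenvalue. Each axis reports its percent of fitted variation
#' (eigenvalue over the sum of positive constrained eigenvalues) and of
#' total variation (over the sum of positive eigenvalues of G). Negative
#' eigenvalues, possible for non-Euclidean resemblances, are reported
#' but excluded from the percentage denominators, with a warning.
#'
#' @inheritParams distlm
#' @return an object of class `dbrda_result`: list with `scores`
#'   (samples x axes), `eig`, `pct_fitted`, `pct_total`, `n_axes`,
#'   `ss_fitted`, `ss_residual`, `ss_total`.
#' @export
dbrda <- function(response, covariates) {
  g <- response_to_gower(response)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(g)
  if (nrow(x) != n) stop("covariates and response sample counts differ")
  h <- hat_matrix(x)
  fitted_g <- h %*% g %*% h
  fitted_g <- (fitted_g + t(fitted_g)) / 2
  e <- eigen(fitted_g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- which(e$values > tol)
  if (length(pos) == 0L) stop("no constrained structure (no positive eigenvalues)")
  q_rank <- qr(cbind(1, x))$rank - 1L
  n_axes <- min(length(pos), q_rank)
  pos <- pos[seq_len(n_axes)]
  eig <- e$values[pos]
  neg_fitted <- e$values[e$values < -tol]
  if (length(neg_fitted) > 0)
    warning("negative constrained eigenvalues excluded from percentages")
  g_eig <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  total_pos <- sum(g_eig[g_eig > tol])
  scores <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig), n_axes)
  colnames(scores) <- paste0("dbRDA", seq_len(n_axes))
  ss_fit <- sum(h * g)
  structure(list(scores = scores, eig = eig,
                 pct_fitted = 100 * eig / sum(eig),
                 pct_total = 100 * eig / total_pos,
                 n_axes = n_axes,
                 ss_fitted = ss_fit, ss_residual = sum(diag(g)) - ss_fit,
                 ss_total = sum(diag(g))),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: %d constrained axes; fitted SS %.4g of total %.4g\n",
              x$n_axes, x$ss_fitted, x$ss_total))
  for (k in seq_len(x$n_axes))
    cat(sprintf("  axis %d: %.2f%% of fitted, %.2f%% of total\n",
                k, x$pct_fitted[k], x$pct_total[k]))
  invisible(x)
}

#' Build the DistLM sample table from seasonal series and climate
#'
#' Joins monthly zone summaries of the index with the monthly climate
#' records, yielding one row per (zone, year, month) with the zone mean
#' index as response and Tmx/Tmn/Prep as covariates — the sample layout
#' behind the climate attribution.
#'
#' @param series data.frame from [seasonal_series()] (optionally with a
#'   `zone` column if several zones are bound together).
#' @param climate data.frame with columns year, month, tmx_c, tmn_c,
#'   prep_mm (see [read_climate()]).
#' @return data.frame with response column `savi_mean` and covariates.
#' @export
attribution_table <- function(series, climate) {
  keep <- !is.na(series$mean)
  df <- merge(series[keep, ], climate, by = c("year", "month"))
  if (nrow(df) == 0L) stop("no overlapping (year, month) rows")
  df$savi_mean <- df$mean
  df
}

#' Read a monthly climate table
#'
#' CSV with columns year, month, tmx, tmn, prep. With
#' `terraclimate_scaling = TRUE` the temperature columns are stored x10
#' and converted to degrees Celsius (gain 0.1); precipitation is mm.
#' Validates `tmx_c >= tmn_c` and `prep_mm >= 0`.
#'
#' @param path CSV path.
#' @param terraclimate_scaling apply the x0.1 temperature conversion.
#' @return data.frame with year, month, tmx_c, tmn_c, prep_mm.
#' @export
read_climate <- function(path, terraclimate_scaling = TRUE) {
  df <- utils::read.csv(path)
  need <- c("year", "month", "tmx", "tmn", "prep")
  if (!all(need %in% names(df)))
    stop(sprintf("climate CSV must have columns %s", paste(need, collapse = ", ")))
  gain <- if (terraclimate_scaling) 0.1 else 1
  out <- data.frame(year = as.integer(df$year), month = as.integer(df$month),
                    tmx_c = df$tmx * gain, tmn_c = df$tmn * gain,
                    prep_mm = df$prep)
  if (any(out$tmx_c < out$tmn_c)) stop("tmx < tmn in climate table")
  if (any(out$prep_mm < 0)) stop("negative precipitation")
  out
}
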