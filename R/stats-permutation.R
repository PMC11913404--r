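one_sample_t <- function(B) {
  n <- nrow(B)
  mu <- colMeans(B)
  sdv <- col_sds(B)
  tt <- mu / (sdv / sqrt(n))
  tt[sdv == 0] <- ifelse(mu[sdv == 0] == 0, 0, Inf * sign(mu[sdv == 0]))
  tt
}

# largest cluster mass only (hot path of the permutation null)
max_cluster_mass <- function(tt, crit) {
  supra <- abs(tt) > crit
  if (!any(supra)) return(0)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mx <- 0
  for (k in which(r$values)) {
    mx <- max(mx, sum(abs(tt[starts[k]:ends[k]])))
  }
  mx
}

# maximal runs of supra-threshold |t|; returns start/end column and mass
find_clusters <- function(tt, crit) {
  supra <- abs(tt) > crit
  if (!any(supra)) {
    return(data.frame(start = integer(), end = integer(), mass = numeric(),
                      sign = integer()))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = starts[keep],
    end = ends[keep],
    mass = vapply(keep, function(k) sum(abs(tt[starts[k]:ends[k]])),
                  numeric(1)),
    sign = vapply(keep, function(k) {
      as.integer(sign(sum(tt[starts[k]:ends[k]])))
    }, integer(1)))
}

#' Cluster-based permutation test on a subjects x timepoints weight matrix
#'
#' Group-level inference on per-timepoint regression weights that controls
#' the family-wise error over time. At each timepoint a two-sided one-sample
#' t statistic is computed across subjects; contiguous runs of timepoints
#' whose |t| exceeds the two-sided critical value at `alpha_forming` form
#' clusters, each scored by its mass (sum of |t| within the run). The null
#' distribution of the maximal cluster mass is built by randomly sign-flipping
#' whole subject rows (the exchangeability unit under the null of zero mean
#' weight) and re-extracting the maximum mass; each observed cluster gets
#' `p = (1 + #(null max >= mass)) / (1 + n_perm)` (add-one estimator, so p is
#' never 0).
#'
#' @param B `N_S x T` matrix of per-subject weight series (e.g. `B_RI` from
#'   [stack_beta_series()]); at least 5 rows.
#' @param alpha_forming cluster-forming alpha (default 0.05, two-sided).
#' @param n_perm number of sign-flip permutations (default 10000; >= 100).
#' @param seed optional RNG seed.
#' @param time_axis optional times (s) used to report cluster intervals.
#' @return a `cluster_result`: data.frame `clusters` (`start`, `end` column
#'   indices, `t_start`, `t_end` seconds when a time axis is given, `mass`,
#'   `sign`, `p`), plus the per-timepoint `t` series, `crit`,
#'   `alpha_forming`, `n_perm`, `seed`.
#' @export
cluster_permutation <- function(B, alpha_forming = 0.05, n_perm = 10000L,
                                seed = NULL, time_axis = NULL) {
  B <- as.matrix(B)
  nS <- nrow(B)
  if (nS < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (n_perm < 100L) stop("need at least 100 permutations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  crit <- stats::qt(1 - alpha_forming / 2, df = nS - 1L)
  tt <- one_sample_t(B)
  cl <- find_clusters(tt, crit)
  # sign-flip null: colSums(B^2) is flip-invariant, only means change
  n <- nS
  ss <- colSums(B^2)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- (S %*% B) / n                       # permuted column means
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)  # permuted column variances
  Tp <- M / sqrt(V / n)
  Tp[!is.finite(Tp)] <- 0
  null_max <- vapply(seq_len(n_perm), function(b) {
    max_cluster_mass(Tp[b, ], crit)
  }, numeric(1))
  cl$p <- vapply(cl$mass, function(m) (1 + sum(null_max >= m)) / (1 + n_perm),
                 numeric(1))
  if (!is.null(time_axis)) {
    cl$t_start <- time_axis[cl$start]
    cl$t_end <- time_axis[cl$end]
  }
  structure(list(clusters = cl, t = tt, crit = crit,
                 alpha_forming = alpha_forming, n_perm = n_perm, seed = seed,
                 null_max = null_max, time_axis = time_axis),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> alpha_forming = %g, %d permutation(s)\n",
              x$alpha_forming, x$n_perm))
  if (!nrow(x$clusters)) {
    cat("no supra-threshold clusters\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' Significant clusters of a cluster result
#'
#' @param x a `cluster_result`.
#' @param alpha significance level (default 0.05).
#' @return the rows of `x$clusters` with `p < alpha`.
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cluster_result"))
  x$clusters[x$clusters$p < alpha, , drop = FALSE]
}
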