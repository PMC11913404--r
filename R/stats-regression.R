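#' Behavioral covariates for a set of aligned blocks
#'
#' Bundles the three per-block behavioral metrics used as regressors:
#' session elapsed `SE = T_b / T_S`, block velocity `BV = 1 / (T_f - T_b)`,
#' and the routine index `RI` of the cycle the block belongs to.
#'
#' @param se,bv,ri numeric vectors of equal length, all finite.
#' @return object of class `covariate_set`.
#' @export
covariate_set <- function(se, bv, ri) {
  if (length(se) != length(bv) || length(se) != length(ri)) {
    stop("covariate vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(se)) || any(!is.finite(bv)) || any(!is.finite(ri))) {
    stop("covariates must be finite (drop blocks outside any cycle first)",
         call. = FALSE)
  }
  structure(list(se = se, bv = bv, ri = ri), class = "covariate_set")
}

#' Build covariates for one subject's blocks of a given type
#'
#' Computes the per-cycle routine index, assigns it to every member block
#' (`RI(x) = RI(C)` for the enclosing cycle `C`), and returns the covariates
#' for blocks of `block_type` that belong to a cycle, along with a row
#' filter aligned with `blocks`.
#'
#' @param blocks data.frame from [segment_blocks()].
#' @param cycles data.frame from [segment_cycles()].
#' @param block_type which block type to keep.
#' @param transformation,L passed to [routine_index()].
#' @return list with `keep` (logical over `blocks` rows), `covariates`
#'   (a [covariate_set()] for the kept rows) and `ri_by_cycle`.
#' @export
block_covariates <- function(blocks, cycles, block_type,
                             transformation = "square_root", L = 60) {
  ri_by_cycle <- routine_index(cycles$duration, transformation, L = L)
  cyc <- assign_block_cycles(blocks, cycles)
  keep <- blocks$block_type == block_type & !is.na(cyc)
  list(keep = keep,
       covariates = covariate_set(blocks$se[keep], blocks$bv[keep],
                                  ri_by_cycle[cyc[keep]]),
       ri_by_cycle = ri_by_cycle)
}

design_matrix <- function(X, K) {
  if (length(X$se) != K) {
    stop("covariate length does not match the aligned matrix", call. = FALSE)
  }
  Z <- cbind(intercept = 1, se = X$se, bv = X$bv, ri = X$ri)
  if (qr(Z)$rank < ncol(Z)) {
    cm <- suppressWarnings(stats::cor(Z[, -1, drop = FALSE]))
    cm[!upper.tri(cm)] <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    stop(sprintf("rank-deficient design (covariates '%s' and '%s' collinear)",
                 colnames(cm)[worst[1]], colnames(cm)[worst[2]]),
         call. = FALSE)
  }
  Z
}

#' Per-timepoint regression of aligned activity on behavioral covariates
#'
#' Fits, independently at every timepoint `t`, the ordinary least squares
#' model `Y(:, t) = b0(t) + b_SE(t) SE + b_BV(t) BV + b_RI(t) RI` over the K
#' aligned blocks of one subject. The resulting coefficient time series
#' (one per covariate) are what group-level cluster inference runs on.
#'
#' @param M an `aligned_matrix` (K rows).
#' @param X a [covariate_set()] of length K.
#' @return a `beta_series`: list of numeric vectors `beta0`, `beta_se`,
#'   `beta_bv`, `beta_ri` (length T) plus `time_axis`.
#' @export
pointwise_regression <- function(M, X) {
  stopifnot(inherits(M, "aligned_matrix"), inherits(X, "covariate_set"))
  K <- nrow(M$Y)
  if (K < 8L) stop("need at least 8 blocks (rows) to fit 4 coefficients",
                   call. = FALSE)
  Z <- design_matrix(X, K)
  co <- qr.coef(qr(Z), M$Y)  # 4 x T
  structure(list(beta0 = co[1, ], beta_se = co[2, ], beta_bv = co[3, ],
                 beta_ri = co[4, ], time_axis = M$time_axis),
            class = "beta_series")
}

#' Stack per-subject coefficient series into group matrices
#'
#' @param series list of `beta_series`, one per subject, on a common time
#'   axis.
#' @return list of `N_S x T` matrices `B_SE`, `B_BV`, `B_RI` (and `B0`),
#'   plus `time_axis`.
#' @export
stack_beta_series <- function(series) {
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "beta_series")))
  Tn <- length(series[[1]]$time_axis)
  if (!all(vapply(series, function(s) length(s$time_axis) == Tn, logical(1)))) {
    stop("subjects have differing time axes; align with a common window",
         call. = FALSE)
  }
  grab <- function(f) do.call(rbind, lapply(series, `[[`, f))
  list(B0 = grab("beta0"), B_SE = grab("beta_se"), B_BV = grab("beta_bv"),
       B_RI = grab("beta_ri"), time_axis = series[[1]]$time_axis)
}

#' Regression of interval AUC on behavioral covariates
#'
#' Per-subject OLS of summed activity over a prespecified interval on the
#' behavioral covariates: `sum_t Y(:, t) = b0 + b_SE SE + b_BV BV + b_RI RI`.
#' Group-level inference on the per-subject weights uses
#' [wilcoxon_across_subjects()].
#'
#' @param auc numeric K-vector from [interval_auc()].
#' @param X a [covariate_set()] of length K.
#' @return named numeric vector `c(intercept, se, bv, ri)`.
#' @export
auc_regression <- function(auc, X) {
  stopifnot(inherits(X, "covariate_set"))
  K <- length(auc)
  if (K < 8L) stop("need at least 8 blocks", call. = FALSE)
  Z <- design_matrix(X, K)
  co <- qr.coef(qr(Z), auc)
  stats::setNames(co, c("intercept", "se", "bv", "ri"))
}

#' One-sample Wilcoxon signed-rank test across subjects
#'
#' Tests whether per-subject regression weights deviate from zero. Exact
#' null for 25 or fewer subjects (the usual cohort scale), normal
#' approximation with continuity correction above.
#'
#' @param weights numeric vector, one weight per subject (at least 5, not
#'   all zero).
#' @return two-sided p-value.
#' @export
wilcoxon_across_subjects <- function(weights) {
  if (length(weights) < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (all(weights == 0)) stop("degenerate test: all weights are zero",
                              call. = FALSE)
  suppressWarnings(
    stats::wilcox.test(weights, mu = 0, exact = length(weights) <= 25L,
                       correct = TRUE)$p.value)
}

#' Pre/post event comparison of average activity
#'
#' Compares mean activity just before (`[-half, 0]`) and just after
#' (`[0, half]`) an event across subjects: per subject, activity is averaged
#' over blocks and timepoints in each half-window; the per-subject pre/post
#' pairs are compared by a two-sided paired Wilcoxon signed-rank test.
#'
#' @param mats list of `aligned_matrix` objects, one per subject, whose time
#'   axes cover `[-half, half]` around the event.
#' @param half half-window in seconds (default 0.5).
#' @return list with `p`, and data.frame `subjects` of per-subject `pre` and
#'   `post` means.
#' @export
pre_post_comparison <- function(mats, half = 0.5) {
  stopifnot(length(mats) >= 2L,
            all(vapply(mats, inherits, logical(1), "aligned_matrix")))
  pre <- post <- numeric(length(mats))
  for (i in seq_along(mats)) {
    ta <- mats[[i]]$time_axis
    if (min(ta) > -half + 1e-9 || max(ta) < half - 1e-9) {
      stop("time axis does not cover the pre/post windows", call. = FALSE)
    }
    pre[i] <- mean(interval_auc(mats[[i]], c(-half, 0))) /
      sum(ta >= -half - 1e-9 & ta <= 1e-9)
    post[i] <- mean(interval_auc(mats[[i]], c(0, half))) /
      sum(ta >= -1e-9 & ta <= half + 1e-9)
  }
  d <- pre - post
  p <- if (all(d == 0)) 1 else suppressWarnings(
    stats::wilcox.test(pre, post, paired = TRUE,
                       exact = length(d) <= 25L)$p.value)
  list(p = p, subjects = data.frame(pre = pre, post = post))
}

#' Shuffle-null validation of the routine index against behavior curves
#'
#' For each subject, the coefficient of determination (squared Pearson
#' correlation) between that subject's routine-index curve and a behavioral
#' measure curve over common session-elapsed bins. The null re-pairs each
#' behavior curve with another subject's routine-index curve (derangement by
#' default, so no subject keeps its own curve) and recomputes the mean R2;
#' `p = (1 + #(null mean >= observed mean)) / (1 + n_shuffles)`.
#'
#' @param ri_curves subjects x bins matrix of routine-index values on a
#'   common session-elapsed grid (NA for unoccupied bins).
#' @param behavior_curves matching matrix of the behavioral measure.
#' @param n_shuffles number of null re-pairings (default 1000).
#' @param seed optional RNG seed.
#' @param scheme `"derangement"` (default) or `"permutation"` (self-pairing
#'   allowed).
#' @return list with `r2` (per-subject observed R2), `mean_r2`, `null_means`,
#'   `p`, and `dropped` (subjects with fewer than 3 common occupied bins).
#' @export
shuffle_r2_validation <- function(ri_curves, behavior_curves,
                                  n_shuffles = 1000L, seed = NULL,
                                  scheme = c("derangement", "permutation")) {
  scheme <- match.arg(scheme)
  ri_curves <- as.matrix(ri_curves)
  behavior_curves <- as.matrix(behavior_curves)
  stopifnot(identical(dim(ri_curves), dim(behavior_curves)))
  nS <- nrow(ri_curves)
  if (nS < 2L) stop("need at least 2 subjects", call. = FALSE)
  r2_pair <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])^2
  }
  r2 <- vapply(seq_len(nS), function(i) {
    r2_pair(ri_curves[i, ], behavior_curves[i, ])
  }, numeric(1))
  dropped <- which(is.na(r2))
  if (length(dropped)) {
    warning(sprintf("dropping %d subject(s) with < 3 usable common bins",
                    length(dropped)))
  }
  keep <- which(!is.na(r2))
  if (length(keep) < 2L) stop("fewer than 2 usable subjects", call. = FALSE)
  obs <- mean(r2[keep])
  if (!is.null(seed)) set.seed(seed)
  draw_pairing <- function() {
    repeat {
      pm <- sample(keep)
      if (scheme == "permutation" || all(pm != keep)) return(pm)
    }
  }
  null_means <- vapply(seq_len(n_shuffles), function(b) {
    pm <- draw_pairing()
    mean(vapply(seq_along(keep), function(j) {
      r2_pair(ri_curves[pm[j], ], behavior_curves[keep[j], ])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(r2 = r2, mean_r2 = obs, null_means = null_means,
       p = (1 + sum(null_means >= obs)) / (1 + n_shuffles),
       dropped = dropped)
}

#' Per-subject routine-index curve over session-elapsed bins
#'
#' Helper for [shuffle_r2_validation()]: bins a subject's cycles by session
#' elapsed and averages the routine index within each bin.
#'
#' @param cycles data.frame from [segment_cycles()].
#' @param n_bins number of session-elapsed bins (default 10).
#' @param transformation,L passed to [routine_index()].
#' @return numeric vector of length `n_bins` (NA for empty bins).
#' @export
ri_curve <- function(cycles, n_bins = 10L, transformation = "square_root",
                     L = 60) {
  b <- se_bins(n_bins)
  out <- rep(NA_real_, n_bins)
  if (!nrow(cycles)) return(out)
  ri <- routine_index(cycles$duration, transformation, L = L)
  bin <- findInterval(cycles$se, b$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  for (k in seq_len(n_bins)) if (any(bin == k)) out[k] <- mean(ri[bin == k])
  out
}
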