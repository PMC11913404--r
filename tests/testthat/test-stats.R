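mk_aligned <- function(Y, fps = 30) {
  structure(list(Y = Y, time_axis = (seq_len(ncol(Y)) - 1) / fps,
                 block_refs = data.frame(row = seq_len(nrow(Y))),
                 mode = "head_fixed", window_length = (ncol(Y) - 1) / fps,
                 dropped = integer()),
            class = "aligned_matrix")
}

test_that("pointwise regression recovers exact linear structure", {
  set.seed(81)
  K <- 40; Tn <- 25
  ri <- runif(K, 0.8, 2)
  se <- runif(K)
  bv <- runif(K, 0.2, 3)
  X <- covariate_set(se, bv, ri)
  Y <- matrix(0.5 + 2 * ri, K, Tn)
  bs <- pointwise_regression(mk_aligned(Y), X)
  expect_equal(unname(bs$beta_ri), rep(2, Tn), tolerance = 1e-9)
  expect_equal(unname(bs$beta0), rep(0.5, Tn), tolerance = 1e-9)
  expect_equal(unname(bs$beta_se), rep(0, Tn), tolerance = 1e-9)
})

test_that("pointwise regression equals a per-timepoint lm() loop", {
  set.seed(82)
  K <- 30; Tn <- 12
  X <- covariate_set(runif(K), runif(K, 0.2, 3), runif(K, 0.8, 2))
  Y <- matrix(rnorm(K * Tn), K, Tn)
  bs <- pointwise_regression(mk_aligned(Y), X)
  for (t in seq_len(Tn)) {
    co <- coef(lm(Y[, t] ~ X$se + X$bv + X$ri))
    expect_equal(unname(bs$beta0[t]), unname(co[1]), tolerance = 1e-9)
    expect_equal(unname(bs$beta_se[t]), unname(co[2]), tolerance = 1e-9)
    expect_equal(unname(bs$beta_bv[t]), unname(co[3]), tolerance = 1e-9)
    expect_equal(unname(bs$beta_ri[t]), unname(co[4]), tolerance = 1e-9)
  }
})

test_that("pointwise regression enforces its preconditions", {
  X <- covariate_set(runif(6), runif(6), runif(6))
  expect_error(pointwise_regression(mk_aligned(matrix(0, 6, 5)), X),
               "at least 8")
  se <- runif(20)
  Xc <- covariate_set(se, runif(20), 2 * se + 1)
  expect_error(pointwise_regression(mk_aligned(matrix(rnorm(200), 20, 10)),
                                    Xc),
               "collinear")
  expect_error(covariate_set(c(1, NA), c(1, 2), c(1, 2)), "finite")
})

test_that("null OLS weights behave as theory predicts", {
  set.seed(83)
  K <- 60
  X <- covariate_set(runif(K), runif(K, 0.2, 3), runif(K, 0.8, 2))
  Z <- cbind(1, X$se, X$bv, X$ri)
  # theoretical SD of beta_ri under unit noise
  sd_theory <- sqrt(solve(crossprod(Z))[4, 4])
  b <- replicate(1000, {
    y <- rnorm(K)
    qr.coef(qr(Z), y)[4]
  })
  expect_lt(abs(mean(b)), 3 * sd_theory / sqrt(1000))
  expect_lt(abs(sd(b) / sd_theory - 1), 0.1)
})

test_that("cluster permutation finds nothing in flat or empty input", {
  B0 <- matrix(0, 8, 40)
  r <- cluster_permutation(B0, n_perm = 200, seed = 1)
  expect_equal(nrow(r$clusters), 0)
  expect_error(cluster_permutation(matrix(0, 3, 10), n_perm = 200),
               "at least 5")
  expect_error(cluster_permutation(matrix(0, 8, 10), n_perm = 50),
               "at least 100")
})

test_that("an injected group bump is localized with small p", {
  set.seed(84)
  hits <- 0
  for (rep in 1:20) {
    B <- bump_matrix(11, 50, 18:32, bump = 1.6)
    r <- cluster_permutation(B, n_perm = 1000, seed = rep)
    sig <- significant_clusters(r, 0.01)
    if (nrow(sig)) {
      cover <- max(vapply(seq_len(nrow(sig)), function(k) {
        length(intersect(sig$start[k]:sig$end[k], 18:32)) / 15
      }, numeric(1)))
      if (cover >= 0.8) hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("cluster p-values respect permutation symmetries and never reach 0", {
  set.seed(85)
  B <- bump_matrix(9, 40, 10:20, bump = 1.2)
  r1 <- cluster_permutation(B, n_perm = 4000, seed = 9)
  # subject relabeling: identical clusters, p equal up to Monte Carlo error
  r2 <- cluster_permutation(B[sample(9), ], n_perm = 4000, seed = 9)
  expect_equal(r1$clusters$mass, r2$clusters$mass)
  expect_equal(r1$clusters$p, r2$clusters$p, tolerance = 0.05)
  # a global sign flip flips cluster signs but not p
  r3 <- cluster_permutation(-B, n_perm = 4000, seed = 9)
  expect_equal(r3$clusters$p, r1$clusters$p)
  expect_equal(r3$clusters$sign, -r1$clusters$sign)
  expect_true(all(r1$clusters$p >= 1 / 4001))
  # p decreases as the injected effect grows (fixed noise seeds)
  p_at <- vapply(c(0.5, 1, 2), function(amp) {
    set.seed(86)
    Bk <- bump_matrix(9, 40, 10:20, bump = amp)
    r <- cluster_permutation(Bk, n_perm = 500, seed = 10)
    if (nrow(r$clusters)) min(r$clusters$p) else 1
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("AUC regression + Wilcoxon reproduce the extreme-case closed form", {
  set.seed(87)
  K <- 20
  slopes <- 3 + 0.1 * (1:11)  # distinct per-subject effects, all one sign
  weights <- vapply(1:11, function(s) {
    X <- covariate_set(runif(K), runif(K, 0.2, 3), runif(K, 0.8, 2))
    auc <- slopes[s] * X$ri
    unname(auc_regression(auc, X)["ri"])
  }, numeric(1))
  expect_equal(weights, slopes, tolerance = 1e-9)
  # all weights share a sign: the exact two-sided signed-rank p is 2 (1/2)^11
  expect_equal(wilcoxon_across_subjects(weights), 2 * (1 / 2)^11,
               tolerance = 1e-12)
  expect_error(wilcoxon_across_subjects(3), "at least 5")
  expect_error(wilcoxon_across_subjects(rep(0, 8)), "degenerate")
})

test_that("pre/post comparison: direction, degeneracy, and sign symmetry", {
  set.seed(88)
  fps <- 30
  mk_pp <- function(drop) {
    ta <- seq(-0.5, 0.5, by = 1 / fps)
    Y <- matrix(rnorm(12 * length(ta), 0, 0.1), 12)
    Y[, ta > 0] <- Y[, ta > 0] - drop
    structure(list(Y = Y, time_axis = ta, block_refs = NULL,
                   mode = "peri_event", window_length = 1,
                   dropped = integer()),
              class = "aligned_matrix")
  }
  mats <- lapply(1:8, function(i) mk_pp(1))
  r <- pre_post_comparison(mats)
  expect_lt(r$p, 0.05)
  expect_true(all(r$subjects$pre > r$subjects$post))
  # identical halves give p = 1
  flat <- lapply(1:6, function(i) mk_pp(0))
  for (m in seq_along(flat)) {
    flat[[m]]$Y[] <- rep(abs(flat[[m]]$Y[, 1]), ncol(flat[[m]]$Y))
  }
  expect_equal(pre_post_comparison(flat)$p, 1)
  # sign-flipped data give the identical two-sided p
  neg <- lapply(mats, function(m) { m$Y <- -m$Y; m })
  expect_equal(pre_post_comparison(neg)$p, r$p)
})

test_that("shuffle-R2 validation: perfect linearity, oracle R2, null behavior", {
  set.seed(89)
  nS <- 10; nb <- 10
  ri <- matrix(rnorm(nS * nb, 1.5, 0.4), nS)
  beh <- 0.3 + 0.7 * ri + matrix(0, nS, nb)
  r <- shuffle_r2_validation(ri, beh, n_shuffles = 200, seed = 1)
  expect_equal(unname(r$r2), rep(1, nS), tolerance = 1e-12)
  expect_equal(r$mean_r2, 1)
  # independent curves: observed mean R2 is unremarkable under the null
  beh2 <- matrix(rnorm(nS * nb), nS)
  r2 <- shuffle_r2_validation(ri, beh2, n_shuffles = 200, seed = 2)
  expect_gt(r2$p, 0.05)
  # R2 equals the squared-correlation oracle pair by pair
  for (k in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    rr <- shuffle_r2_validation(rbind(a, a), rbind(b, b), n_shuffles = 10,
                                seed = k, scheme = "permutation")
    expect_equal(unname(rr$r2[1]), cor(a, b)^2, tolerance = 1e-12)
  }
  # derangements never self-pair (degenerate 2-subject case: always swapped)
  rd <- shuffle_r2_validation(ri[1:2, ], beh2[1:2, ], n_shuffles = 50,
                              seed = 3)
  swapped <- cor(ri[2, ], beh2[1, ])^2 / 2 + cor(ri[1, ], beh2[2, ])^2 / 2
  expect_true(all(abs(rd$null_means - swapped) < 1e-12))
})

test_that("subjects with too few usable bins are dropped from the R2 pool", {
  ri <- rbind(c(1, 2, 3, 4), c(1, NA, NA, NA), c(2, 1, 4, 3))
  beh <- rbind(c(2, 3, 4, 5), c(1, 2, 3, 4), c(5, 1, 2, 2))
  expect_warning(r <- shuffle_r2_validation(ri, beh, n_shuffles = 20,
                                            seed = 4),
                 "dropping 1 subject")
  expect_equal(r$dropped, 2L)
})

test_that("ri_curve bins cycles by session elapsed", {
  cycles <- data.frame(cycle = 1:4, t_start = c(1, 2, 3, 4),
                       t_end = c(2, 3, 4, 5),
                       duration = c(60, 15, 15, 240),
                       n_blocks = 3, se = c(0.05, 0.06, 0.55, 0.95))
  rc <- ri_curve(cycles, n_bins = 10)
  expect_equal(rc[1], mean(c(1, 2)))
  expect_equal(rc[6], 2)
  expect_equal(rc[10], 0.5)
  expect_true(all(is.na(rc[c(2:5, 7:9)])))
})

test_that("nested mixed models respect likelihood ordering and DF accounting", {
  set.seed(90)
  d <- lmm_sim_data(b_ri = 0.8, b_se = 0, b_bv = 0.8)
  tab <- lrt_model_comparison(d)
  expect_equal(tab$model, c("RI", "RI + SE", "RI + BV", "Full"))
  expect_equal(tab$df, c(6L, 8L, 8L, 10L))
  full_ll <- tab$ll[tab$model == "Full"]
  expect_true(all(tab$ll <= full_ll + 1e-6))
  expect_equal(tab$delta_df, c(4L, 2L, 2L, NA))
  expect_true(all(tab$lr_stat[1:3] >= -1e-6))
  # dropping the active BV term is punished; dropping the null SE term is not
  expect_lt(tab$p[tab$model == "RI + SE"], 0.05)
  expect_gt(tab$p[tab$model == "RI + BV"], 0.05)
})

test_that("activity_long stacks matrices with their covariates", {
  set.seed(91)
  Y <- matrix(rnorm(8 * 4), 8, 4)
  M <- mk_aligned(Y)
  X <- covariate_set(runif(8), runif(8, 0.5, 2), runif(8, 1, 2))
  d <- activity_long(list(a = M), list(a = X))
  expect_equal(nrow(d), 32)
  expect_equal(d$activity[d$block == 3 & d$time == M$time_axis[2]], Y[3, 2])
  expect_equal(unique(d$ri[d$block == 5]), X$ri[5])
})
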