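RI_TRANSFORMATIONS <- c("linear", "logarithmic", "reciprocal", "square_root")

ri_transform_fun <- function(transformation) {
  switch(transformation,
         linear = identity,
         logarithmic = log,
         reciprocal = function(u) 1 / u,
         square_root = sqrt,
         stop("unknown transformation: ", transformation, call. = FALSE))
}

#' Routine index of a cycle
#'
#' The routine index quantifies how tightly the animal's behavior adheres to
#' the reward-seeking routine: `RI(C) = f(L / T(C))` where `T(C)` is the time
#' (s) taken to complete cycle `C`, `L = 60` is the number of seconds per
#' minute, and `f` is a normalizing transformation, by default the square
#' root. Faster cycle completion means a larger index.
#'
#' @param cycle_duration cycle duration(s) in seconds, vectorized.
#' @param transformation one of `"linear"`, `"logarithmic"`, `"reciprocal"`,
#'   `"square_root"` (default).
#' @param L seconds per minute; fixed at 60.
#' @return numeric vector of routine indices.
#' @examples
#' routine_index(c(60, 15, 240))  # 1, 2, 0.5
#' @export
routine_index <- function(cycle_duration, transformation = "square_root",
                          L = 60) {
  transformation <- match.arg(transformation, RI_TRANSFORMATIONS)
  if (any(!is.finite(cycle_duration)) || any(cycle_duration <= 0)) {
    stop("cycle durations must be positive and finite", call. = FALSE)
  }
  ri_transform_fun(transformation)(L / cycle_duration)
}

#' Kolmogorov-Smirnov distance from normality
#'
#' One-sample K-S distance between the empirical CDF of the sample,
#' standardized by its own mean and SD, and the standard normal CDF
#' (Lilliefors-style standardization; the statistic, not its p-value, is
#' what downstream transformation selection compares, so no null-distribution
#' correction is applied).
#'
#' @param x numeric sample, at least 3 finite values (cohort-level selection
#'   additionally requires 5 cycles per subject; see
#'   [select_transformation()]).
#' @return the K-S statistic `D` in `[0, 1]`.
#' @export
ks_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 finite values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample: zero variance", call. = FALSE)
  z <- (x - mean(x)) / s
  unname(suppressWarnings(stats::ks.test(z, "pnorm")$statistic))
}

#' Select the routine-index transformation by the K-S criterion
#'
#' Applies each candidate transformation to `L / T(C)` for every subject's
#' cycle durations, measures the per-subject K-S distance from normality of
#' the transformed index, and selects the transformation with the smallest
#' group-mean distance. Each alternative is also compared against the
#' reference (square root) by a paired t-test, with a Dunnett-style
#' adjustment obtained by max-|t| sign-flip resampling over the joint set of
#' contrasts.
#'
#' @param durations named list, one numeric vector of cycle durations (s)
#'   per subject; subjects with fewer than 5 usable cycles or a degenerate
#'   transformed sample are dropped with a warning.
#' @param transformations candidate transformations (default all four).
#' @param reference transformation the others are compared against
#'   (default `"square_root"`).
#' @param L seconds per minute.
#' @param n_boot resamples for the max-|t| adjustment (default 10000; 0
#'   skips the adjustment and reports only paired-t p-values).
#' @param seed optional RNG seed for the resampling.
#' @return a `transformation_report`: list with `ks` (subject x
#'   transformation matrix), `mean`, `sem`, `comparisons` (data.frame of
#'   paired t and p-values vs the reference, plus adjusted p when
#'   `n_boot > 0`), and `selected`.
#' @export
select_transformation <- function(durations,
                                  transformations = RI_TRANSFORMATIONS,
                                  reference = "square_root", L = 60,
                                  n_boot = 10000L, seed = NULL) {
  transformations <- match.arg(transformations, RI_TRANSFORMATIONS,
                               several.ok = TRUE)
  stopifnot(reference %in% transformations)
  if (!is.list(durations) || length(durations) < 2L) {
    stop("need a list of cycle durations for at least 2 subjects",
         call. = FALSE)
  }
  subj <- names(durations) %||% paste0("subject", seq_along(durations))
  ks <- matrix(NA_real_, length(durations), length(transformations),
               dimnames = list(subj, transformations))
  for (i in seq_along(durations)) {
    d <- durations[[i]]
    d <- d[is.finite(d) & d > 0]
    if (length(d) < 5L) next  # subject lacks enough cycles; row stays NA
    ks[i, ] <- vapply(transformations, function(tr) {
      tryCatch(ks_statistic(routine_index(d, tr, L = L)),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  ok <- rowSums(is.na(ks)) == 0L
  if (any(!ok)) {
    warning(sprintf("dropping %d subject(s) with unusable cycle samples",
                    sum(!ok)))
    ks <- ks[ok, , drop = FALSE]
  }
  if (nrow(ks) < 2L) {
    stop("fewer than 2 subjects survive the K-S preconditions", call. = FALSE)
  }
  mu <- colMeans(ks)
  sem <- col_sds(ks) / sqrt(nrow(ks))
  others <- setdiff(transformations, reference)
  cmp <- data.frame(transformation = others, t = NA_real_, p_paired = NA_real_,
                    p_adjusted = NA_real_, stringsAsFactors = FALSE)
  if (length(others)) {
    diffs <- ks[, others, drop = FALSE] - ks[, reference]
    tstat <- function(d) {
      s <- stats::sd(d)
      if (s == 0) return(if (mean(d) == 0) 0 else Inf * sign(mean(d)))
      mean(d) / (s / sqrt(length(d)))
    }
    cmp$t <- apply(diffs, 2, tstat)
    cmp$p_paired <- vapply(others, function(tr) {
      tryCatch(stats::t.test(ks[, tr], ks[, reference], paired = TRUE)$p.value,
               error = function(e) NA_real_)  # constant differences
    }, numeric(1))
    if (n_boot > 0L) {
      if (!is.null(seed)) set.seed(seed)
      nS <- nrow(diffs)
      centered <- sweep(diffs, 2, colMeans(diffs))  # enforce the null
      maxt <- replicate(n_boot, {
        s <- sample(c(-1, 1), nS, replace = TRUE)
        max(abs(apply(centered * s, 2, tstat)))
      })
      cmp$p_adjusted <- vapply(abs(cmp$t), function(t0) {
        (1 + sum(maxt >= t0)) / (1 + n_boot)
      }, numeric(1))
    }
  }
  structure(list(ks = ks, mean = mu, sem = sem, comparisons = cmp,
                 reference = reference,
                 selected = names(which.min(mu))),
            class = "transformation_report")
}

#' @export
print.transformation_report <- function(x, ...) {
  cat("<transformation_report>\n")
  tab <- data.frame(mean_ks = round(x$mean, 4), sem = round(x$sem, 4))
  print(tab)
  cat("selected:", x$selected, "(reference:", x$reference, ")\n")
  invisible(x)
}

#' Write a transformation report to disk
#'
#' Emits the subject x transformation K-S matrix as CSV and the group
#' summary (means, SEMs, comparisons, selection) as JSON.
#'
#' @param report a `transformation_report` from [select_transformation()].
#' @param csv_path,json_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transformation_report <- function(report, csv_path, json_path) {
  stopifnot(inherits(report, "transformation_report"))
  utils::write.csv(as.data.frame(report$ks), csv_path, row.names = TRUE)
  jsonlite::write_json(
    list(mean = as.list(report$mean), sem = as.list(report$sem),
         comparisons = report$comparisons, reference = report$reference,
         selected = report$selected),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
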