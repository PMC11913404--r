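#' Long-format activity table for mixed-model comparison
#'
#' Stacks aligned activity into the (subject, block, timepoint) records the
#' nested mixed models are fitted on.
#'
#' @param mats named list of `aligned_matrix`, one per subject.
#' @param covs matching list of [covariate_set()] objects.
#' @return data.frame with columns `subject`, `block`, `time` (seconds on the
#'   aligned axis), `activity`, `ri`, `se`, `bv`.
#' @export
activity_long <- function(mats, covs) {
  stopifnot(length(mats) == length(covs), length(mats) >= 1L)
  ids <- names(mats) %||% paste0("subject", seq_along(mats))
  out <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    M <- mats[[i]]; X <- covs[[i]]
    K <- nrow(M$Y); Tn <- ncol(M$Y)
    out[[i]] <- data.frame(
      subject = ids[i],
      block = rep(seq_len(K), times = Tn),
      time = rep(M$time_axis, each = K),
      activity = as.vector(M$Y),
      ri = rep(X$ri, times = Tn),
      se = rep(X$se, times = Tn),
      bv = rep(X$bv, times = Tn),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

lmm_formulas <- function() {
  list(
    "RI"      = activity ~ ri * time + (1 | subject),
    "RI + SE" = activity ~ ri * time + se * time + (1 | subject),
    "RI + BV" = activity ~ ri * time + bv * time + (1 | subject),
    "Full"    = activity ~ ri * time + se * time + bv * time + (1 | subject))
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Tests whether each behavioral covariate earns its place in the
#' per-timepoint regression by fitting four nested linear mixed models to
#' long-format activity data and comparing each restricted model to the full
#' one with a likelihood ratio test. Time enters as a continuous covariate
#' interacting with each behavioral metric (the effect of a metric on
#' activity varies over peri-event time), and subjects contribute a random
#' intercept. Models are fitted by maximum likelihood (not REML) because the
#' comparisons differ in fixed effects. The models are:
#'
#' \describe{
#'   \item{RI}{`activity ~ ri * time + (1 | subject)` (6 parameters)}
#'   \item{RI + SE}{adds `se * time` (8)}
#'   \item{RI + BV}{adds `bv * time` instead (8)}
#'   \item{Full}{all three covariates by time (10)}
#' }
#'
#' @param data long-format data.frame from [activity_long()] (columns
#'   `activity`, `ri`, `se`, `bv`, `time`, `subject`); at least 5 subjects.
#' @param random `"intercept"` (default) or `"ri_slope"` to add a random RI
#'   slope per subject.
#' @return a `model_comparison_table`: data.frame with one row per model -
#'   `model`, `df`, `aic`, `bic`, `ll`, and for each restricted model
#'   `lr_stat`, `delta_df`, `p` (chi-square) versus the full model;
#'   non-converged fits are flagged in `note` and their comparison left `NA`.
#' @export
lrt_model_comparison <- function(data, random = c("intercept", "ri_slope")) {
  random <- match.arg(random)
  need <- c("activity", "ri", "se", "bv", "time", "subject")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$subject)) < 5L) {
    stop("need at least 5 subjects", call. = FALSE)
  }
  forms <- lmm_formulas()
  if (random == "ri_slope") {
    forms <- lapply(forms, function(f) {
      stats::update(f, . ~ . - (1 | subject) + (1 + ri | subject))
    })
  }
  fits <- lapply(forms, function(f) {
    tryCatch(
      lme4::lmer(f, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) e)
  })
  tab <- data.frame(model = names(forms), df = NA_integer_, aic = NA_real_,
                    bic = NA_real_, ll = NA_real_, lr_stat = NA_real_,
                    delta_df = NA_integer_, p = NA_real_, note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (inherits(f, "error")) {
      tab$note[i] <- paste("fit failed:", conditionMessage(f))
      next
    }
    ll <- stats::logLik(f)
    tab$df[i] <- attr(ll, "df")
    tab$ll[i] <- as.numeric(ll)
    tab$aic[i] <- stats::AIC(f)
    tab$bic[i] <- stats::BIC(f)
  }
  full <- which(tab$model == "Full")
  if (!is.na(tab$ll[full])) {
    for (i in seq_len(nrow(tab))) {
      if (i == full || is.na(tab$ll[i])) next
      tab$lr_stat[i] <- 2 * (tab$ll[full] - tab$ll[i])
      tab$delta_df[i] <- tab$df[full] - tab$df[i]
      tab$p[i] <- stats::pchisq(tab$lr_stat[i], df = tab$delta_df[i],
                                lower.tail = FALSE)
    }
  } else {
    tab$note[full] <- paste(tab$note[full], "(comparisons unavailable)")
  }
  structure(tab, class = c("model_comparison_table", "data.frame"),
            fits = fits)
}

#' @export
print.model_comparison_table <- function(x, ...) {
  cat("<model_comparison_table> likelihood-ratio tests vs the full model\n")
  print.data.frame(x[, c("model", "df", "aic", "bic", "ll", "lr_stat",
                         "delta_df", "p")],
                   row.names = FALSE, digits = 6)
  invisible(x)
}
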