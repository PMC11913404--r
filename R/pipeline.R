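#' Default pipeline parameters
#'
#' All tunable parameters of the analysis with their standard values:
#' dF/F windows (0.75 s averaging, 3 s baseline lookback), smoothing
#' (tau 0.2 s, width 1 s), routine index (L = 60, square-root
#' transformation), cluster inference (forming alpha 0.05, 10^4
#' permutations), pre/post half-window 0.5 s, 10 session-elapsed bins.
#'
#' @return named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(avg_window = 0.75, baseline_lookback = 3, tau = 0.2, width = 1,
       L = 60, transformation = "square_root",
       alpha_forming = 0.05, n_perm = 10000L, alpha = 0.05,
       pre = 0.5, post = 0.5, n_bins = 10L,
       min_blocks = 8L, signal = "z", seed = 1L)
}

#' Assemble a pipeline configuration
#'
#' @param subjects data.frame or list with per-subject `id`, `events`
#'   (event log path), `trace` (trace CSV path).
#' @param out_dir output directory for artifacts.
#' @param ... overrides of [pipeline_defaults()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects, out_dir = NULL, ...) {
  params <- utils::modifyList(pipeline_defaults(), list(...))
  structure(list(subjects = subjects, out_dir = out_dir, params = params),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Configs round-trip unchanged so a run can be reproduced from its
#' serialized configuration alone.
#'
#' @param path YAML path.
#' @return a `pipeline_config` (for the reader); `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(raw$subjects, out_dir = raw$out_dir)
  cfg$params <- utils::modifyList(cfg$params, raw$params %||% list())
  cfg
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(list(subjects = config$subjects, out_dir = config$out_dir,
                        params = config$params), path)
  invisible(path)
}

# per-subject behavioral segmentation + trace preprocessing
prepare_subject <- function(stream, trace, params) {
  blocks <- segment_blocks(stream)
  cycles <- segment_cycles(blocks)
  proc <- process_trace(trace, avg_window = params$avg_window,
                        baseline_lookback = params$baseline_lookback,
                        tau = params$tau, width = params$width)
  list(stream = stream, blocks = blocks, cycles = cycles, trace = proc)
}

analysis_block_types <- function() {
  list("rNP-ME" = "tail_fixed", "ME-MX" = "head_fixed")
}

align_subject_type <- function(prep, block_type, mode, window, params) {
  bc <- block_covariates(prep$blocks, prep$cycles, block_type,
                         transformation = params$transformation,
                         L = params$L)
  blks <- prep$blocks[bc$keep, , drop = FALSE]
  if (nrow(blks) < params$min_blocks) return(NULL)
  M <- suppressWarnings(align_blocks(prep$trace, blks, mode = mode,
                                     window = window,
                                     signal = params$signal))
  if (nrow(M$Y) < params$min_blocks) return(NULL)
  surv <- setdiff(seq_len(nrow(blks)), M$dropped)
  X <- covariate_set(bc$covariates$se[surv], bc$covariates$bv[surv],
                     bc$covariates$ri[surv])
  list(M = M, X = X)
}

#' Run the full cohort analysis in memory
#'
#' Executes the whole chain - segmentation, routine index, dF/F
#' preprocessing, block alignment, per-timepoint regression, cluster
#' permutation on the routine-index weights, AUC post-hoc tests on the
#' significant intervals, and the pre/post magazine-entry comparison - on a
#' list of in-memory sessions.
#'
#' For each analyzed block type (`rNP-ME`, tail-fixed to magazine entry;
#' `ME-MX`, head-fixed to magazine entry) the alignment window is half the
#' cohort-mean block duration, shared across subjects so the group weight
#' matrices line up. Subjects contributing fewer than `min_blocks` usable
#' blocks of a type are dropped from that type's analysis with a warning.
#'
#' @param sessions list of per-subject lists with elements `stream`
#'   ([event_stream()]) and `trace` (raw [photometry_trace()]); the
#'   `sessions` element of [simulate_cohort()] works directly.
#' @param params parameter list; defaults from [pipeline_defaults()].
#' @return a `pipeline_result`: per block type the stacked weight matrices,
#'   `cluster_result` on the routine-index weights, AUC Wilcoxon p-values
#'   per covariate and significant interval; plus the pre/post comparison,
#'   per-subject cycle tables, the transformation report, and the seeds and
#'   parameters used.
#' @export
analyze_cohort <- function(sessions, params = pipeline_defaults()) {
  params <- utils::modifyList(pipeline_defaults(), params)
  stopifnot(length(sessions) >= 2L)
  preps <- lapply(sessions, function(s) {
    prepare_subject(s$stream, s$trace, params)
  })
  ids <- vapply(preps, function(p) p$stream$subject_id, "")
  names(preps) <- ids

  durations <- lapply(preps, function(p) p$cycles$duration)
  transformation_report <- tryCatch(
    select_transformation(durations, n_boot = 0L, L = params$L),
    error = function(e) NULL)

  results <- list()
  for (bt in names(analysis_block_types())) {
    mode <- analysis_block_types()[[bt]]
    pooled <- unlist(lapply(preps, function(p) {
      p$blocks$duration[p$blocks$block_type == bt]
    }))
    if (!length(pooled)) next
    window <- mean(pooled) / 2
    aligned <- lapply(preps, align_subject_type, block_type = bt,
                      mode = mode, window = window, params = params)
    ok <- !vapply(aligned, is.null, logical(1))
    if (sum(ok) < 5L) {
      warning(sprintf("block type %s: only %d usable subject(s); skipped",
                      bt, sum(ok)))
      next
    }
    if (any(!ok)) {
      warning(sprintf("block type %s: dropping subject(s) %s (too few blocks)",
                      bt, paste(ids[!ok], collapse = ", ")))
    }
    aligned <- aligned[ok]
    series <- lapply(aligned, function(a) pointwise_regression(a$M, a$X))
    stacked <- stack_beta_series(series)
    clus <- cluster_permutation(stacked$B_RI,
                                alpha_forming = params$alpha_forming,
                                n_perm = params$n_perm, seed = params$seed,
                                time_axis = stacked$time_axis)
    sig <- significant_clusters(clus, params$alpha)
    auc_tests <- lapply(seq_len(nrow(sig)), function(r) {
      iv <- c(sig$t_start[r], sig$t_end[r])
      W <- t(vapply(aligned, function(a) {
        auc_regression(interval_auc(a$M, iv), a$X)
      }, numeric(4)))
      list(interval = iv,
           weights = W,
           p = c(se = wilcoxon_across_subjects(W[, "se"]),
                 bv = wilcoxon_across_subjects(W[, "bv"]),
                 ri = wilcoxon_across_subjects(W[, "ri"])))
    })
    results[[bt]] <- list(mode = mode, window = window,
                          subjects = names(aligned),
                          B = stacked, clusters = clus,
                          significant = sig, auc_tests = auc_tests)
  }

  # pre/post comparison around rewarded magazine entries
  pp_mats <- lapply(preps, function(p) {
    rme <- p$blocks$t_end[p$blocks$block_type == "rNP-ME"]
    if (length(rme) < 2L) return(NULL)
    suppressWarnings(peri_event_matrix(p$trace, rme, pre = params$pre,
                                       post = params$post,
                                       signal = params$signal))
  })
  pp_ok <- !vapply(pp_mats, is.null, logical(1))
  pre_post <- if (sum(pp_ok) >= 2L) pre_post_comparison(pp_mats[pp_ok]) else
    NULL

  structure(list(block_types = results, pre_post = pre_post,
                 transformation_report = transformation_report,
                 cycles = lapply(preps, `[[`, "cycles"),
                 blocks = lapply(preps, `[[`, "blocks"),
                 subjects = ids, params = params),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subject(s)\n", length(x$subjects)))
  for (bt in names(x$block_types)) {
    r <- x$block_types[[bt]]
    sig <- r$significant
    cat(sprintf("  %s (%s, window %.2f s): %d significant cluster(s)\n",
                bt, r$mode, r$window, nrow(sig)))
    for (k in seq_len(nrow(sig))) {
      cat(sprintf("    [%.3f, %.3f] s  mass %.1f  sign %+d  p = %.4g\n",
                  sig$t_start[k], sig$t_end[k], sig$mass[k], sig$sign[k],
                  sig$p[k]))
    }
  }
  if (!is.null(x$pre_post)) {
    cat(sprintf("  pre/post magazine entry: p = %.4g\n", x$pre_post$p))
  }
  if (!is.null(x$transformation_report)) {
    cat("  routine-index transformation:",
        x$transformation_report$selected, "\n")
  }
  invisible(x)
}

#' Run the pipeline from a configuration
#'
#' File-level orchestration: reads each subject's event log and trace,
#' runs [analyze_cohort()], and (when `out_dir` is set) writes the results
#' bundle - `results.json` (clusters, p-values, parameters, seeds, config
#' hash), per-subject beta-series and cycle CSVs, and the transformation
#' report. Stage failures abort with the failing stage named.
#'
#' @param config a `pipeline_config`, or the path to its YAML form.
#' @return the `pipeline_result`, invisibly when writing artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  subs <- config$subjects
  if (is.data.frame(subs)) subs <- split(subs, seq_len(nrow(subs)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  sessions <- stage("load", lapply(subs, function(s) {
    s <- as.list(s)
    if (!file.exists(s$events %||% "")) {
      stop("missing event log for subject ", s$id %||% "?", call. = FALSE)
    }
    if (!file.exists(s$trace %||% "")) {
      stop("missing trace file for subject ", s$id %||% "?", call. = FALSE)
    }
    list(stream = read_events(s$events, subject_id = s$id),
         trace = read_trace(s$trace, subject_id = s$id))
  }))
  res <- stage("analyze", analyze_cohort(sessions, config$params))
  if (!is.null(config$out_dir)) {
    stage("write", write_pipeline_result(res, config))
    return(invisible(res))
  }
  res
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(list(subjects = config$subjects,
                        params = config$params), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_result <- function(res, config) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summ <- list(
    subjects = res$subjects,
    params = res$params,
    config_hash = config_hash(config),
    block_types = lapply(res$block_types, function(r) {
      list(mode = r$mode, window = r$window, subjects = r$subjects,
           clusters = r$clusters$clusters,
           n_perm = r$clusters$n_perm, seed = r$clusters$seed,
           auc_tests = lapply(r$auc_tests, function(a) {
             list(interval = a$interval, p = as.list(a$p))
           }))
    }),
    pre_post_p = if (!is.null(res$pre_post)) res$pre_post$p else NULL,
    transformation = if (!is.null(res$transformation_report))
      res$transformation_report$selected else NULL)
  jsonlite::write_json(summ, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (bt in names(res$block_types)) {
    r <- res$block_types[[bt]]
    tag <- gsub("[^A-Za-z]", "_", bt)
    utils::write.csv(
      data.frame(subject = rep(r$subjects, each = length(r$B$time_axis)),
                 time = rep(r$B$time_axis, times = length(r$subjects)),
                 beta_ri = as.vector(t(r$B$B_RI)),
                 beta_se = as.vector(t(r$B$B_SE)),
                 beta_bv = as.vector(t(r$B$B_BV))),
      file.path(dir, paste0("beta_series_", tag, ".csv")),
      row.names = FALSE)
  }
  cyc <- do.call(rbind, lapply(names(res$cycles), function(id) {
    cbind(subject = id, res$cycles[[id]])
  }))
  utils::write.csv(cyc, file.path(dir, "cycles.csv"), row.names = FALSE)
  if (!is.null(res$transformation_report)) {
    write_transformation_report(res$transformation_report,
                                file.path(dir, "ks_matrix.csv"),
                                file.path(dir, "transformation.json"))
  }
  invisible(dir)
}
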