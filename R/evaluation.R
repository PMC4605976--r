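# Test-set figures of merit, selection overlap, and the pipeline runner.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) sample
#' pairs in which the positive sample scores higher, ties counting one
#' half. Computed from midranks, which is algebraically identical to
#' exhaustive pair counting.
#'
#' @param scores continuous classifier scores (higher = more positive).
#' @param labels two-class labels aligned with `scores`.
#' @param positive label treated as positive (default: larger class).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = NULL) {
  cod <- code_response(labels, positive)
  pos <- cod$y > 0
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Test-set confusion metrics
#'
#' Sensitivity is the percentage of positive-class samples (by convention
#' the larger cohort, e.g. OSAS) correctly predicted; specificity the
#' percentage of negative-class samples (e.g. COPD) correctly predicted;
#' efficiency (non-error rate) the percentage of all test samples
#' correctly classified.
#'
#' @param predicted predicted class labels.
#' @param truth true class labels (both classes must occur).
#' @param positive label counted for sensitivity (default: larger truth
#'   class).
#' @return An `eval_report`: confusion counts plus `sensitivity`,
#'   `specificity`, `efficiency` in percent.
#' @export
confusion_metrics <- function(predicted, truth, positive = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  cod <- code_response(truth, positive)
  pos <- cod$positive
  neg <- cod$negative
  if (!all(predicted %in% c(pos, neg))) {
    stop("predicted labels outside the truth label set", call. = FALSE)
  }
  np <- sum(truth == pos)
  nn <- sum(truth == neg)
  if (np == 0L || nn == 0L) {
    stop("a class is empty in the truth labels", call. = FALSE)
  }
  tp <- sum(truth == pos & predicted == pos)
  tn <- sum(truth == neg & predicted == neg)
  confusion <- table(truth = factor(truth, c(neg, pos)),
                     predicted = factor(predicted, c(neg, pos)))
  structure(list(
    confusion = confusion,
    n = length(truth),
    positive = pos, negative = neg,
    sensitivity = 100 * tp / np,
    specificity = 100 * tn / nn,
    efficiency = 100 * (tp + tn) / (np + nn)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: sensitivity %.2f%%, specificity %.2f%%, efficiency %.2f%% (n = %d, positive = %s)\n",
    x$sensitivity, x$specificity, x$efficiency, x$n, x$positive))
  if (!is.null(x$auc_test)) cat(sprintf("test AUC: %.3f\n", x$auc_test))
  invisible(x)
}

#' Overlap between two selected variable sets
#'
#' Counts the variables common to two selections and expresses them as a
#' rounded percentage of the total number of variables in the block(s)
#' considered (e.g. 7 common EBC variables out of 16 give 44%).
#'
#' @param selection_a,selection_b character vectors of variable names, or
#'   `selection_result` objects.
#' @param block_total total variable count of the block(s) the selections
#'   were made from.
#' @return An `overlap_stat`: `common` names, `n_common`, and integer
#'   `percent`.
#' @export
overlap_stats <- function(selection_a, selection_b, block_total) {
  getvars <- function(s) {
    if (inherits(s, "selection_result")) s$retained else as.character(s)
  }
  a <- getvars(selection_a)
  b <- getvars(selection_b)
  stopifnot(block_total >= 1L)
  common <- intersect(a, b)
  structure(list(common = common, n_common = length(common),
                 block_total = as.integer(block_total),
                 percent = round(100 * length(common) / block_total)),
            class = "overlap_stat")
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("overlap_stat: %d common variables, %d%% of %d\n",
              x$n_common, x$percent, x$block_total))
  invisible(x)
}

#' Run the full discriminant-biomarker pipeline
#'
#' Orchestrates the whole workflow on one block combination: fuse the
#' blocks, split into a balanced model set and a test set (Kennard-Stone
#' per group), optionally select variables by iterated bootstrap VIP
#' and/or bootstrap SR, fit the final PLS-DA model (complexity by LOO) on
#' the model set, and evaluate it on the untouched test set. When both
#' criteria are run, the overlap of their selections is reported.
#'
#' @param config a named list (or path to a YAML/JSON file) with entries:
#'   `csv` (path(s) to metabolite tables, fused if several) or `spec`
#'   (arguments for [synthetic_spec()]); optional `blocks` (block names to
#'   keep), `criterion` (`"none"`, `"VIP"`, `"SR"` or `"both"`; default
#'   `"none"`), `fraction` (0.75), `B` (1000), `A_max` (5), `vip_cutoff`
#'   (0.8), `vip_rounds` (3), `sr_cutoff` (`NULL` = DIVA-derived),
#'   `positive`, `seed`, and `out_dir` to write the report files.
#' @return A `pipeline_report` list: settings, the split plan, and one
#'   result per criterion (model-set bootstrap AUC +/- se, final
#'   complexity, retained variables, test AUC and confusion metrics),
#'   plus the selection overlap when both criteria ran.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  cfg <- config
  cfg$criterion <- match.arg(cfg$criterion %||% "none",
                             c("none", "VIP", "SR", "both"))
  cfg$fraction <- cfg$fraction %||% 0.75
  cfg$B <- as.integer(cfg$B %||% 1000L)
  cfg$A_max <- as.integer(cfg$A_max %||% 5L)
  cfg$vip_cutoff <- cfg$vip_cutoff %||% 0.8
  cfg$vip_rounds <- as.integer(cfg$vip_rounds %||% 3L)
  cfg$seed <- as.integer(cfg$seed %||% 1L)

  # --- assemble the fused table -------------------------------------------
  table <- if (!is.null(cfg$csv)) {
    fuse_blocks(lapply(cfg$csv, read_metabolite_table))
  } else if (!is.null(cfg$spec)) {
    sp <- if (inherits(cfg$spec, "synthetic_spec")) cfg$spec
          else do.call(synthetic_spec, cfg$spec)
    generate_cohort(sp)
  } else {
    stop("config needs either `csv` input paths or a synthetic `spec`",
         call. = FALSE)
  }
  if (!is.null(cfg$blocks)) {
    unknown <- setdiff(cfg$blocks, unique(table$blocks))
    if (length(unknown)) {
      stop("unknown block(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    table <- mt_subset(table,
                       variables = names(table$blocks)[table$blocks %in%
                                                         cfg$blocks])
  }
  positive <- cfg$positive %||% code_response(table$groups)$positive

  # --- split ---------------------------------------------------------------
  plan <- balanced_split(table, fraction = cfg$fraction)
  parts <- split_tables(table, plan)
  seeds <- local_seed(cfg$seed, as.list(sample.int(2^31 - 2, 4)))

  criteria <- switch(cfg$criterion,
                     none = "none", VIP = "VIP", SR = "SR",
                     both = c("VIP", "SR"))
  results <- list()
  selections <- list()
  for (cr in criteria) {
    sel <- NULL
    if (cr == "VIP") {
      sel <- vip_selection_rounds(parts$model, cutoff = cfg$vip_cutoff,
                                  rounds = cfg$vip_rounds, B = cfg$B,
                                  A_max = cfg$A_max, seed = seeds[[1]],
                                  positive = positive)
    } else if (cr == "SR") {
      sel <- sr_selection(parts$model, cutoff = cfg$sr_cutoff, B = cfg$B,
                          A_max = cfg$A_max, seed = seeds[[2]],
                          positive = positive)
    }
    vars <- if (is.null(sel)) colnames(table$values) else sel$retained
    identity_selection <- !is.null(sel) &&
      length(vars) == ncol(table$values)
    model_mt <- mt_subset(parts$model, variables = vars)
    test_mt <- mt_subset(parts$test, variables = vars)
    boot <- bootstrap_plsda(model_mt, B = cfg$B, A_max = cfg$A_max,
                            seed = seeds[[3]], collect = "none",
                            positive = positive)
    A <- select_complexity_loo(model_mt, A_max = cfg$A_max,
                               positive = positive)
    fit <- fit_plsda(model_mt, ncomp = A, positive = positive)
    pred <- predict(fit, test_mt)
    tmet <- confusion_metrics(pred$class, as.character(test_mt$groups),
                             positive = positive)
    tmet$auc_test <- auc(pred$score, as.character(test_mt$groups),
                        positive = positive)
    results[[cr]] <- list(
      criterion = cr,
      n_variables = length(vars),
      variables = vars,
      identity_selection = identity_selection,
      selection = sel,
      complexity = as.integer(A),
      model_auc_mean = boot$auc_mean,
      model_auc_se = boot$auc_se,
      auc_replicates = boot$auc,
      test = tmet
    )
    if (!is.null(sel)) selections[[cr]] <- sel
  }
  overlap <- NULL
  if (length(selections) == 2L) {
    overlap <- overlap_stats(selections$VIP, selections$SR,
                             ncol(table$values))
  }
  report <- structure(list(
    schema = "plsdafuse-report/1",
    settings = list(criterion = cfg$criterion, fraction = cfg$fraction,
                    B = cfg$B, A_max = cfg$A_max,
                    vip_cutoff = cfg$vip_cutoff,
                    vip_rounds = cfg$vip_rounds,
                    sr_cutoff = cfg$sr_cutoff, seed = cfg$seed,
                    positive = positive,
                    blocks = unname(unique(table$blocks)),
                    n_samples = nrow(table$values),
                    n_variables = ncol(table$values)),
    split = plan,
    results = results,
    overlap = overlap
  ), class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("pipeline_report: %d samples x %d variables (%s), B = %d\n",
              s$n_samples, s$n_variables,
              paste(s$blocks, collapse = " + "), s$B))
  print(x$split)
  for (r in x$results) {
    cat(sprintf(
      "  [%s] %d vars, A = %d | model AUC %.3f +/- %.3f | test AUC %.3f | sens %.2f spec %.2f eff %.2f\n",
      r$criterion, r$n_variables, r$complexity, r$model_auc_mean,
      r$model_auc_se, r$test$auc_test, r$test$sensitivity,
      r$test$specificity, r$test$efficiency))
  }
  if (!is.null(x$overlap)) print(x$overlap)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full bundle), `metrics.csv` (one row per
#' criterion: model-set mean AUC and its standard error, test AUC,
#' sensitivity / specificity / efficiency to two decimals, complexity,
#' variable count) and per-criterion `auc_replicates_<criterion>.csv`
#' histograms of the bootstrap AUC estimates.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- rapply(unclass(report), function(x) {
    if (is.table(x)) as.data.frame(x) else x
  }, how = "replace")
  for (cr in names(ser$results)) {
    ser$results[[cr]]$selection$audit <- NULL  # matrices; keep JSON lean
  }
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  rows <- lapply(report$results, function(r) {
    data.frame(criterion = r$criterion, n_variables = r$n_variables,
               complexity = r$complexity,
               model_auc = round(r$model_auc_mean, 3),
               model_auc_se = round(r$model_auc_se, 3),
               auc_test = round(r$test$auc_test, 3),
               sensitivity = round(r$test$sensitivity, 2),
               specificity = round(r$test$specificity, 2),
               efficiency = round(r$test$efficiency, 2))
  })
  write.csv(do.call(rbind, rows), file.path(dir, "metrics.csv"),
            row.names = FALSE)
  for (r in report$results) {
    write.csv(data.frame(replicate = seq_along(r$auc_replicates),
                         auc = r$auc_replicates),
              file.path(dir, sprintf("auc_replicates_%s.csv",
                                     r$criterion)),
              row.names = FALSE)
  }
  invisible(dir)
}
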