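# Bootstrap engine and the VIP / selectivity-ratio selection procedures.

#' Standard error of a bootstrap AUC estimate
#'
#' Uncertainty of the mean bootstrap AUC over `b` replicates:
#' `sqrt( sum_i (theta*_i - mean(theta*))^2 / (b - 1) )`, i.e. the sample
#' standard deviation of the per-replicate estimates.
#'
#' @param aucs numeric vector of per-replicate AUC estimates (length >= 2).
#' @return Non-negative scalar; 0 iff all replicates agree.
#' @export
auc_se <- function(aucs) {
  aucs <- as.numeric(aucs)
  if (length(aucs) < 2L) {
    stop("need at least two bootstrap AUC estimates", call. = FALSE)
  }
  sqrt(sum((aucs - mean(aucs))^2) / (length(aucs) - 1))
}

#' Bootstrap PLS-DA with per-replicate complexity selection
#'
#' For each of `B` bootstrap samples the model-set samples are resampled
#' with replacement *within each group* (stratified, so no replicate loses
#' a class), autoscaling is refit on the resample, the model complexity is
#' re-selected by leave-one-out cross-validation (capped at `A_max`), a
#' PLS-DA model is fit, and the AUC is recorded on the out-of-bag samples.
#' VIP and/or selectivity-ratio profiles are collected per replicate and
#' averaged. Replicates whose out-of-bag set would miss a whole group are
#' redrawn (counted in `redraws`).
#'
#' @param x model-set [metabolite_table()] (preferably balanced), or a
#'   numeric matrix with `y` supplied.
#' @param y class labels when `x` is a matrix.
#' @param B number of bootstrap replicates.
#' @param A_max complexity cap for the per-replicate LOO selection.
#' @param seed integer seed; the run is reproducible given it.
#' @param collect which variable profiles to record.
#' @param oob compute the per-replicate AUC on out-of-bag samples
#'   (default); `FALSE` scores the in-bag resample instead (optimistic).
#' @param refit_scaling refit autoscaling on each resample (default);
#'   `FALSE` reuses the model-set scaling.
#' @param sr_reconstructed selectivity ratio on the A-component
#'   reconstruction of X instead of raw scaled X (default `FALSE`; the
#'   reconstruction is degenerate for single-component replicates).
#' @param positive class coded +1 (default: larger class).
#' @return A `bootstrap_run`: per-replicate `auc` and `ncomp`, `auc_mean`,
#'   `auc_se`, per-replicate `vip` / `sr` matrices and their per-variable
#'   means, plus the call settings.
#' @export
bootstrap_plsda <- function(x, y = NULL, B = 1000L, A_max = 5L,
                            seed = NULL,
                            collect = c("both", "vip", "sr", "none"),
                            oob = TRUE, refit_scaling = TRUE,
                            sr_reconstructed = FALSE, positive = NULL) {
  collect <- match.arg(collect)
  if (inherits(x, "metab_table")) {
    y <- x$groups
    x <- x$values
  }
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  cod <- code_response(y, positive)
  B <- as.integer(B)
  stopifnot(B >= 2L)
  n <- nrow(X)
  by_group <- split(seq_len(n), cod$y)
  redraws <- 0L
  idx <- local_seed(seed, {
    draw_col <- function() {
      unlist(lapply(by_group, function(r) {
        sample(r, length(r), replace = TRUE)
      }), use.names = FALSE)
    }
    m <- matrix(0L, n, B)
    for (b in seq_len(B)) {
      repeat {
        cand <- draw_col()
        oob_rows <- setdiff(seq_len(n), cand)
        ok <- !oob ||
          all(vapply(by_group, function(r) any(r %in% oob_rows), TRUE))
        if (ok) break
        redraws <- redraws + 1L
      }
      m[, b] <- cand
    }
    m
  })
  res <- cpp_bootstrap(X, cod$y, idx - 1L, as.integer(A_max),
                       collect %in% c("vip", "both"),
                       collect %in% c("sr", "both"),
                       oob, refit_scaling, sr_reconstructed)
  out <- list(B = B, A_max = as.integer(A_max),
              auc = as.numeric(res$auc),
              auc_mean = mean(res$auc),
              auc_se = auc_se(res$auc),
              ncomp = as.integer(res$ncomp),
              seed = seed, oob = oob, redraws = redraws,
              variables = colnames(X),
              y_coding = c(negative = cod$negative,
                           positive = cod$positive))
  if (!is.null(res$vip)) {
    colnames(res$vip) <- colnames(X)
    out$vip <- res$vip
    out$vip_mean <- colMeans(res$vip)
  }
  if (!is.null(res$sr)) {
    colnames(res$sr) <- colnames(X)
    out$sr <- res$sr
    out$sr_mean <- colMeans(res$sr)
  }
  class(out) <- "bootstrap_run"
  out
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat(sprintf(
    "bootstrap_run: B = %d, mean AUC = %.3f +/- %.3f (%s), median A = %g\n",
    x$B, x$auc_mean, x$auc_se,
    if (x$oob) "out-of-bag" else "in-bag", median(x$ncomp)))
  invisible(x)
}

new_selection_result <- function(criterion, cutoff, rounds, retained,
                                 audit, seed) {
  structure(list(criterion = criterion, cutoff = cutoff,
                 rounds = rounds, retained = retained, audit = audit,
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result (%s): %d variables retained after %d round(s), cut-off %s\n",
    x$criterion, length(x$retained), x$rounds,
    paste(signif(x$cutoff, 3), collapse = ", ")))
  invisible(x)
}

#' Iterated bootstrap VIP selection
#'
#' Runs the bootstrap PLS-DA engine on the currently retained variables and
#' removes those whose bootstrap-average VIP score falls below the cut-off;
#' the procedure is repeated (default three rounds), since a single VIP
#' pass typically leaves too many variables. Rounds stop early when nothing
#' is dropped or fewer than two variables remain.
#'
#' @param table model-set [metabolite_table()].
#' @param cutoff VIP cut-off (default 0.8).
#' @param rounds maximum selection rounds (default 3).
#' @param B,A_max,seed,... passed to [bootstrap_plsda()].
#' @return A `selection_result` with the retained variables (ordered by
#'   final average VIP, descending) and a per-round audit trail.
#' @export
vip_selection_rounds <- function(table, cutoff = 0.8, rounds = 3L,
                                 B = 1000L, A_max = 5L, seed = NULL, ...) {
  stopifnot(inherits(table, "metab_table"), cutoff >= 0, rounds >= 1L)
  round_seeds <- if (is.null(seed)) rep(list(NULL), rounds)
    else local_seed(seed, as.list(sample.int(2^31 - 2, rounds)))
  keep <- colnames(table$values)
  audit <- list()
  done <- 0L
  last_mean <- NULL
  for (r in seq_len(rounds)) {
    cur <- mt_subset(table, variables = keep)
    run <- bootstrap_plsda(cur, B = B, A_max = A_max,
                           seed = round_seeds[[r]], collect = "vip", ...)
    vm <- run$vip_mean
    drop <- names(vm)[vm < cutoff]
    audit[[r]] <- list(round = r, vip_mean = vm, dropped = drop,
                       auc_mean = run$auc_mean, auc_se = run$auc_se)
    done <- r
    last_mean <- vm
    if (length(drop) == length(keep)) {
      stop("all variables fell below the VIP cut-off ", cutoff,
           "; consider a lower cut-off", call. = FALSE)
    }
    keep <- setdiff(keep, drop)
    if (length(drop) == 0L || length(keep) < 2L) break
  }
  kept_scores <- sort(last_mean[keep], decreasing = TRUE)
  new_selection_result("VIP", cutoff, done, names(kept_scores), audit,
                       seed)
}

#' Bootstrap selectivity-ratio selection
#'
#' One bootstrap pass collecting selectivity ratios; variables whose
#' average SR falls below the cut-off are discarded. When `cutoff` is
#' `NULL` it is derived from the discriminating-variable (DIVA) test via
#' [diva_mccr()]. Variables with an infinite average SR are always
#' retained.
#'
#' @param table model-set [metabolite_table()].
#' @param cutoff SR cut-off; `NULL` to derive it with the DIVA test.
#' @param B,A_max,seed,... passed to [bootstrap_plsda()].
#' @param diva_args list of arguments forwarded to [diva_mccr()] when the
#'   cut-off is derived.
#' @return A `selection_result`; its `mccr` element carries the DIVA curve
#'   when one was computed.
#' @export
sr_selection <- function(table, cutoff = NULL, B = 1000L, A_max = 5L,
                         seed = NULL, diva_args = list(), ...) {
  stopifnot(inherits(table, "metab_table"))
  seeds <- if (is.null(seed)) list(NULL, NULL)
    else local_seed(seed, as.list(sample.int(2^31 - 2, 2)))
  run <- bootstrap_plsda(table, B = B, A_max = A_max, seed = seeds[[1]],
                         collect = "sr", ...)
  curve <- NULL
  if (is.null(cutoff)) {
    curve <- do.call(diva_mccr, c(list(run, table, seed = seeds[[2]]),
                                  diva_args))
    cutoff <- curve$cutoff
  }
  stopifnot(is.numeric(cutoff), cutoff >= 0)
  sm <- run$sr_mean
  keep <- names(sm)[sm >= cutoff | is.infinite(sm)]
  if (length(keep) == 0L) {
    stop("no variable reaches the SR cut-off ", cutoff,
         "; consider a lower cut-off", call. = FALSE)
  }
  audit <- list(list(round = 1L, sr_mean = sm,
                     dropped = setdiff(names(sm), keep),
                     auc_mean = run$auc_mean, auc_se = run$auc_se))
  res <- new_selection_result("SR", cutoff, 1L,
                              names(sort(sm[keep], decreasing = TRUE)),
                              audit, seed)
  res$mccr <- curve
  res
}

#' Discriminating-variable (DIVA) test for the SR cut-off
#'
#' Bins variables into equal-width intervals of their bootstrap-average
#' selectivity ratio and estimates, per interval, the mean correct
#' classification rate (MCCR) of the member variables used as univariate
#' optimal-threshold discriminators, evaluated over seeded stratified
#' train/test half-splits. The MCCR rises with SR for discriminating
#' variables, and the proposed cut-off is the lower edge of the first
#' interval whose MCCR exceeds `threshold` percent. If no interval
#' qualifies, the lower edge of the best-MCCR interval is used.
#'
#' @param bootstrap a [bootstrap_plsda()] run with SR collected.
#' @param table the model-set [metabolite_table()] the run was made from.
#' @param intervals number of SR intervals (reduced, with a message, when
#'   fewer variables than intervals are available).
#' @param reps evaluation half-splits per variable.
#' @param threshold MCCR (percent) an interval must exceed to set the
#'   cut-off.
#' @param seed integer seed for the half-splits.
#' @param positive class coded +1 (default: larger class).
#' @return An `mccr_curve`: interval `edges`, per-interval `mccr`
#'   (percent) and variable `counts`, and the chosen `cutoff`.
#' @export
diva_mccr <- function(bootstrap, table, intervals = 10L, reps = 200L,
                      threshold = 60, seed = NULL, positive = NULL) {
  stopifnot(inherits(bootstrap, "bootstrap_run"),
            inherits(table, "metab_table"))
  if (is.null(bootstrap$sr_mean)) {
    stop("bootstrap run carries no selectivity ratios; rerun with ",
         "collect = \"sr\" or \"both\"", call. = FALSE)
  }
  sm <- bootstrap$sr_mean
  p <- length(sm)
  intervals <- as.integer(intervals)
  if (intervals > p) {
    message("more intervals (", intervals, ") than variables (", p,
            "); using ", p, " intervals")
    intervals <- p
  }
  finite <- sm[is.finite(sm)]
  hi <- if (length(finite)) max(finite) else 1
  edges <- seq(0, hi, length.out = intervals + 1L)
  bin <- findInterval(sm, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  bin[!is.finite(sm) | bin > intervals] <- intervals
  cod <- code_response(table$groups, positive)
  X <- table$values[, names(sm), drop = FALSE]
  n <- nrow(X)
  by_group <- split(seq_len(n), cod$y)
  trainidx <- local_seed(seed, {
    vapply(seq_len(reps), function(r) {
      unlist(lapply(by_group, function(rows) {
        sort(sample(rows, floor(length(rows) / 2)))
      }), use.names = FALSE)
    }, integer(sum(vapply(by_group,
                          function(rows) floor(length(rows) / 2), 0))))
  })
  ccr <- as.numeric(cpp_mccr(X, as.integer(cod$y > 0), trainidx - 1L))
  names(ccr) <- names(sm)
  mccr <- vapply(seq_len(intervals), function(j) {
    if (any(bin == j)) 100 * mean(ccr[bin == j]) else NA_real_
  }, numeric(1))
  counts <- tabulate(bin, nbins = intervals)
  over <- which(!is.na(mccr) & mccr > threshold)
  cutoff <- if (length(over)) {
    edges[min(over)]
  } else {
    message("no SR interval exceeds an MCCR of ", threshold,
            "%; falling back to the best interval's lower edge")
    edges[which.max(mccr)]
  }
  structure(list(edges = edges, mccr = mccr, counts = counts,
                 per_variable_ccr = ccr, cutoff = cutoff,
                 threshold = threshold),
            class = "mccr_curve")
}

#' @export
print.mccr_curve <- function(x, ...) {
  cat("mccr_curve: cut-off", signif(x$cutoff, 3), "at MCCR threshold",
      x$threshold, "%\n")
  df <- data.frame(from = head(x$edges, -1), to = x$edges[-1],
                   n = x$counts, mccr = round(x$mccr, 1))
  print(df, row.names = FALSE)
  invisible(x)
}
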