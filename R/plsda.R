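# Two-class PLS-DA via NIPALS PLS1 on a +/-1 coded response.

code_response <- function(y, positive = NULL) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) {
      stop("numeric y must be coded +1 / -1", call. = FALSE)
    }
    if (length(unique(y)) < 2L) stop("single-class y", call. = FALSE)
    return(list(y = as.numeric(y), negative = "-1", positive = "1"))
  }
  f <- droplevels(as.factor(y))
  if (nlevels(f) != 2L) {
    stop("y must have exactly two classes, got ", nlevels(f), call. = FALSE)
  }
  if (is.null(positive)) {
    # convention: the larger class is the positive one (ties: second level)
    tab <- table(f)
    positive <- if (tab[1] > tab[2]) names(tab)[1] else names(tab)[2]
  }
  stopifnot(positive %in% levels(f))
  negative <- setdiff(levels(f), positive)
  list(y = ifelse(as.character(f) == positive, 1, -1),
       negative = negative, positive = positive)
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS1 regression of a +1/-1 coded class variable on the variable
#' matrix. The class cut-off on the predicted response is 0, which is the
#' natural threshold for a balanced model set. Autoscaling is fit on the
#' training rows and stored with the model so new samples are projected
#' with the training statistics.
#'
#' @param x numeric matrix (samples x variables) or [metabolite_table()].
#' @param y class labels (factor/character, or +/-1 numeric); ignored when
#'   `x` is a metabolite table, whose groups are used.
#' @param ncomp model complexity A (number of latent variables).
#' @param scale autoscale internally (default). With `scale = FALSE` the
#'   input is taken as already scaled.
#' @param positive class coded +1; defaults to the larger class.
#' @return A `plsda_model`: weights `W` (unit-norm columns), loadings `P`,
#'   scores `T`, y-loadings `q`, per-component explained y-sum-of-squares
#'   `ssy`, regression vector `b` (and `B`, one column per sub-complexity),
#'   `scaling`, the y coding and the scaled training matrix.
#' @export
fit_plsda <- function(x, y = NULL, ncomp = 2L, scale = TRUE,
                      positive = NULL) {
  if (inherits(x, "metab_table")) {
    y <- x$groups
    x <- x$values
  }
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  cod <- code_response(y, positive)
  ncomp <- as.integer(ncomp)
  stopifnot(ncomp >= 1L)
  if (scale) {
    sc <- autoscale(X)
    Xs <- sc$values
    params <- sc$params
  } else {
    Xs <- X
    params <- structure(list(mean = setNames(rep(0, ncol(X)), colnames(X)),
                             sd = setNames(rep(1, ncol(X)), colnames(X))),
                        class = "scaling_params")
  }
  fit <- cpp_nipals(Xs, cod$y, ncomp)
  if (fit$ncomp < ncomp) {
    stop("requested complexity ", ncomp, " exceeds the rank of X (",
         fit$ncomp, " components available)", call. = FALSE)
  }
  dimnames(fit$W) <- dimnames(fit$P) <- dimnames(fit$B) <-
    list(colnames(X), paste0("comp", seq_len(ncomp)))
  rownames(fit$T) <- rownames(X)
  b <- fit$B[, ncomp]
  structure(
    list(ncomp = ncomp, W = fit$W, P = fit$P, T = fit$T,
         q = as.numeric(fit$q), ssy = as.numeric(fit$ssy),
         b = b, B = fit$B, scaling = params, cutoff = 0,
         y_coding = c(negative = cod$negative, positive = cod$positive),
         y = cod$y, X_scaled = Xs),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "plsda_model: %d variables, %d samples, complexity A = %d\n",
    nrow(x$W), nrow(x$T), x$ncomp))
  cat(sprintf("coding: %s = -1, %s = +1; cut-off %g\n",
              x$y_coding[["negative"]], x$y_coding[["positive"]],
              x$cutoff))
  invisible(x)
}

#' Predict classes for new samples
#'
#' Applies the model's stored autoscaling, projects on the regression
#' vector and thresholds the continuous score at the model cut-off (0). A
#' score exactly on the cut-off is assigned to the negative-coded class.
#'
#' @param object a [fit_plsda()] model.
#' @param newdata matrix or [metabolite_table()] with the model's
#'   variables (matched by name).
#' @param ... unused.
#' @return List with `score` (continuous predicted response) and `class`
#'   (character labels).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "metab_table")) newdata$values
       else as.matrix(newdata)
  vars <- rownames(object$W)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(vars)) {
      stop("newdata has ", ncol(X), " variables; model needs ",
           length(vars), call. = FALSE)
    }
    colnames(X) <- vars
  }
  if (!all(vars %in% colnames(X))) {
    stop("newdata is missing model variables: ",
         paste(setdiff(vars, colnames(X)), collapse = ", "), call. = FALSE)
  }
  X <- X[, vars, drop = FALSE]
  Xs <- autoscale(X, object$scaling)$values
  score <- drop(Xs %*% object$b)
  cls <- ifelse(score > object$cutoff, object$y_coding[["positive"]],
                object$y_coding[["negative"]])
  list(score = score, class = cls)
}

#' Select PLS-DA complexity by leave-one-out cross-validation
#'
#' For every complexity `a = 1..A_max` the LOO misclassification rate is
#' computed with the autoscaling refit inside each fold; the smallest
#' complexity attaining the minimum rate is returned (parsimony as the
#' tie-break).
#'
#' @param x matrix or [metabolite_table()] (raw scale).
#' @param y class labels (see [fit_plsda()]).
#' @param A_max largest complexity to consider.
#' @param positive class coded +1.
#' @return Integer complexity, with the per-complexity LOO error rates as
#'   attribute `"loo_error"`.
#' @export
select_complexity_loo <- function(x, y = NULL, A_max = 5L,
                                  positive = NULL) {
  if (inherits(x, "metab_table")) {
    y <- x$groups
    x <- x$values
  }
  cod <- code_response(y, positive)
  A_max <- max(1L, as.integer(A_max))
  rates <- as.numeric(cpp_loo_misclass(as.matrix(x), cod$y, A_max))
  a <- which.min(rates)  # first minimum = smallest complexity
  structure(as.integer(a), loo_error = rates)
}

#' VIP scores of a fitted PLS-DA model
#'
#' Variable importance in projection: for variable `j`,
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm
#' component weights `w_a` and `SSY_a` the y-sum-of-squares explained by
#' component `a`. By construction the mean of the squared VIP scores over
#' the `p` variables is 1, so 1 (or a slightly laxer 0.8) is the usual
#' influence cut-off.
#'
#' @param model a [fit_plsda()] model.
#' @return Named numeric vector of VIP scores (all `>= 0`).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  v <- as.numeric(cpp_vip(model$W, model$ssy))
  names(v) <- rownames(model$W)
  v
}

#' Target projection of a PLS-DA model
#'
#' Collapses the A-component model onto its single predictive direction:
#' the normalized regression vector `w_TP = b / ||b||`. Scores, loadings
#' and per-variable explained / residual sums of squares are computed on
#' the raw scaled X (default, the standard selectivity-ratio formulation,
#' well defined at any complexity) or on the A-component reconstruction
#' `T P'` of X.
#'
#' @param model a [fit_plsda()] model.
#' @param x optional matrix to project (already autoscaled); defaults to
#'   the model's training matrix.
#' @param reconstructed project the A-component reconstruction `T P'`
#'   rather than the scaled X itself (note the reconstruction is rank-A, so
#'   at A = 1 every residual vanishes and all ratios become infinite).
#' @return A `target_projection` object: `w_tp`, `t_tp`, `p_tp`,
#'   per-variable `explained`, `residual` and `total` sums of squares.
#' @export
target_projection <- function(model, x = NULL, reconstructed = FALSE) {
  stopifnot(inherits(model, "plsda_model"))
  if (sqrt(sum(model$b^2)) < 1e-12) {
    stop("regression vector has zero norm; target projection undefined",
         call. = FALSE)
  }
  Xs <- if (is.null(x)) model$X_scaled else as.matrix(x)
  Tm <- model$T
  if (!is.null(x)) Tm <- Xs %*% model$W %*%
      solve(t(model$P) %*% model$W)  # scores of the supplied matrix
  tp <- cpp_target_projection(Xs, Tm, model$P, model$b, reconstructed)
  vars <- rownames(model$W)
  out <- list(w_tp = setNames(as.numeric(tp$w_tp), vars),
              t_tp = as.numeric(tp$t_tp),
              p_tp = setNames(as.numeric(tp$p_tp), vars),
              explained = setNames(as.numeric(tp$explained), vars),
              residual = setNames(as.numeric(tp$residual), vars),
              reconstructed = reconstructed)
  out$total <- out$explained + out$residual
  class(out) <- "target_projection"
  out
}

#' Selectivity ratio
#'
#' Per-variable ratio of the variance explained by the target-projected
#' predictive component to the residual variance left after the
#' projection. A residual below `1e-12` of the variable's total sum of
#' squares yields `Inf`, which sorts above every finite ratio (and such
#' variables are always retained by SR selection).
#'
#' @param tp a [target_projection()] result.
#' @return Named numeric vector of selectivity ratios (`>= 0`, possibly
#'   `Inf`).
#' @export
selectivity_ratio <- function(tp) {
  stopifnot(inherits(tp, "target_projection"))
  sr <- ifelse(tp$residual < 1e-12 * pmax(tp$total, 1),
               Inf, tp$explained / tp$residual)
  setNames(sr, names(tp$explained))
}
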