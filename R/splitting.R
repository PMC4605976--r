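#' Kennard-Stone sample selection
#'
#' Deterministic max-min selection of `k` representative rows: the first
#' two picks are the mutually most distant pair (Euclidean), and every
#' subsequent pick maximizes its minimum distance to the rows already
#' selected. Distance ties are broken toward the lowest row index so the
#' result is fully reproducible.
#'
#' @param X numeric matrix, candidates in rows (autoscale beforehand when
#'   variables live on different scales).
#' @param k number of rows to select, `1 <= k <= nrow(X)`.
#' @return Integer vector of selected row indices in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop("k must be between 1 and nrow(X) = ", n, call. = FALSE)
  }
  if (n == 1L) return(1L)
  D <- as.matrix(dist(X))
  pair <- which(D == max(D), arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
  pair <- pair[order(pair[, 1], pair[, 2])[1], ]
  sel <- as.integer(pair)
  if (k == 1L) return(sel[1L])
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- unname(which.max(mind))   # ties: lowest index (first maximum)
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

#' Balanced model/test split via per-group Kennard-Stone
#'
#' Selects `floor(fraction * min(group sizes))` samples from each group
#' with the Kennard-Stone algorithm run on that group's autoscaled data, so
#' the model set is balanced (equal count per group) and representative;
#' the remaining samples of both groups form the test set. With the default
#' cohort of 18 vs 28 samples and `fraction = 0.75` this yields a 13+13
#' model set and a 5+15 test set.
#'
#' @param table a [metabolite_table()] (typically the fused multiblock
#'   table).
#' @param fraction fraction of the smaller group to place in the model set.
#' @param scale_scope `"per_group"` (default) fits the autoscaling used for
#'   the distance computation on each group's own rows; `"global"` fits it
#'   once on all samples.
#' @return A `split_plan`: lists `model` and `test` of sample ids per
#'   group, plus `fraction` and the per-group model count `k`.
#' @export
balanced_split <- function(table, fraction = 0.75,
                           scale_scope = c("per_group", "global")) {
  stopifnot(inherits(table, "metab_table"),
            is.numeric(fraction), fraction > 0, fraction < 1)
  scale_scope <- match.arg(scale_scope)
  g <- table$groups
  sizes <- table(g)
  k <- floor(fraction * min(sizes))
  if (k < 2L) {
    stop("degenerate split: floor(fraction * smaller group) = ", k,
         "; need at least 2 model samples per group", call. = FALSE)
  }
  glob <- if (scale_scope == "global") autoscale(table$values)$values
  model <- list(); test <- list()
  for (lv in levels(g)) {
    rows <- which(g == lv)
    Xg <- if (scale_scope == "global") glob[rows, , drop = FALSE]
          else autoscale(table$values[rows, , drop = FALSE])$values
    picked <- kennard_stone(Xg, k)
    ids <- rownames(table$values)[rows]
    model[[lv]] <- ids[picked]
    test[[lv]] <- setdiff(ids, ids[picked])
  }
  structure(list(model = model, test = test, fraction = fraction,
                 k = as.integer(k)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: model %s | test %s (fraction %.2f)\n",
              paste(sprintf("%s: %d", names(x$model),
                            lengths(x$model)), collapse = " + "),
              paste(sprintf("%s: %d", names(x$test),
                            lengths(x$test)), collapse = " + "),
              x$fraction))
  invisible(x)
}

#' Materialize a split plan into model and test tables
#'
#' @param table the [metabolite_table()] the plan was built from.
#' @param plan a [balanced_split()] `split_plan`.
#' @return List with `model` and `test` metabolite tables.
#' @export
split_tables <- function(table, plan) {
  stopifnot(inherits(table, "metab_table"), inherits(plan, "split_plan"))
  pick <- function(ids) mt_subset(table, samples = unlist(ids,
                                                          use.names = FALSE))
  list(model = pick(plan$model), test = pick(plan$test))
}

#' Read / write a split plan as JSON
#'
#' Plans are stored by sample id (not position) so they survive reordering
#' of the underlying table.
#'
#' @param plan a `split_plan`.
#' @param path file path.
#' @return `write_split_plan()` returns `path` invisibly;
#'   `read_split_plan()` returns a `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(model = as.list(x$model), test = as.list(x$test),
                 fraction = x$fraction, k = as.integer(x$k)),
            class = "split_plan")
}
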