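#' Sample-by-metabolite concentration table
#'
#' The unit of data every pipeline stage consumes and produces: a numeric
#' samples x variables matrix together with a binary group label per sample
#' and a block tag (biofluid of origin) per variable. Variable names carry
#' their block as a `"<block>__<metabolite>"` prefix so fused tables remain
#' traceable to their source fluid.
#'
#' @param values numeric matrix, samples in rows. Row names are sample ids
#'   (generated if absent); column names are variable names.
#' @param groups factor or character of length `nrow(values)` with exactly
#'   two distinct labels.
#' @param blocks named character vector mapping each variable name to its
#'   block. If `NULL`, block tags are parsed from `"<block>__<name>"` column
#'   names, falling back to a single block `"X"`.
#' @return An object of class `metab_table` with elements `values`,
#'   `groups` and `blocks`.
#' @examples
#' x <- matrix(rlnorm(20), 5, 4,
#'   dimnames = list(paste0("s", 1:5), paste0("serum__m", 1:4)))
#' mt <- metabolite_table(x, rep(c("COPD", "OSAS"), c(2, 3)))
#' mt
#' @export
metabolite_table <- function(values, groups, blocks = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("`values` must have variable (column) names", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("variable names must be unique across blocks", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing values are not allowed in a metabolite table", call. = FALSE)
  }
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != nrow(values)) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  if (nlevels(groups) != 2L) {
    stop("exactly two distinct group labels are required, got ",
         nlevels(groups), call. = FALSE)
  }
  if (is.null(blocks)) {
    nm <- colnames(values)
    has <- grepl("__", nm, fixed = TRUE)
    blocks <- ifelse(has, sub("__.*$", "", nm), "X")
    names(blocks) <- nm
  }
  if (!all(colnames(values) %in% names(blocks))) {
    stop("every variable needs a block tag", call. = FALSE)
  }
  blocks <- blocks[colnames(values)]
  structure(
    list(values = values, groups = groups, blocks = blocks),
    class = "metab_table"
  )
}

#' @export
print.metab_table <- function(x, ...) {
  tab <- table(x$blocks)
  cat(sprintf(
    "metab_table: %d samples x %d variables (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", ")
  ))
  gt <- table(x$groups)
  cat(sprintf("groups: %s\n",
              paste(sprintf("%s = %d", names(gt), as.integer(gt)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.metab_table <- function(x) dim(x$values)

#' Subset a metabolite table
#'
#' @param x a [metabolite_table()].
#' @param samples,variables row / column selectors (ids, names, logical or
#'   integer indices); `NULL` keeps everything.
#' @return A `metab_table`.
#' @export
mt_subset <- function(x, samples = NULL, variables = NULL) {
  stopifnot(inherits(x, "metab_table"))
  ri <- if (is.null(samples)) seq_len(nrow(x$values)) else samples
  ci <- if (is.null(variables)) seq_len(ncol(x$values)) else variables
  v <- x$values[ri, ci, drop = FALSE]
  metabolite_table(v, x$groups[if (is.character(ri))
    match(ri, rownames(x$values)) else ri], x$blocks[colnames(v)])
}

#' Read / write a metabolite table as CSV
#'
#' The on-disk layout is one header row then one row per sample: first
#' column `sample_id`, second column `group`, remaining columns named
#' `"<block>__<metabolite>"`.
#'
#' @param path file path.
#' @return `read_metabolite_table()` returns a `metab_table`;
#'   `write_metabolite_table()` returns `path` invisibly.
#' @export
read_metabolite_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    stop("expected columns: sample_id, group, then variables", call. = FALSE)
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- as.character(df[[1]])
  metabolite_table(vals, df[[2]])
}

#' @rdname read_metabolite_table
#' @param x a `metab_table`.
#' @export
write_metabolite_table <- function(x, path) {
  stopifnot(inherits(x, "metab_table"))
  df <- data.frame(sample_id = rownames(x$values),
                   group = as.character(x$groups),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fuse several single-fluid tables into one multiblock table
#'
#' Low-level data fusion: the blocks' variables are concatenated column-wise
#' into a single matrix (autoscaling of the fused matrix happens downstream).
#' Samples are matched by id; every sample must be present in every block,
#' mirroring a fusion design that keeps only individuals with all fluids
#' collected. Rows of later tables are realigned to the sample order of the
#' first.
#'
#' @param tables list of [metabolite_table()] objects.
#' @return A fused `metab_table` preserving block tags.
#' @export
fuse_blocks <- function(tables) {
  if (inherits(tables, "metab_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "metab_table")))
  if (length(tables) == 1L) return(tables[[1L]])
  ids <- rownames(tables[[1L]]$values)
  for (i in seq_along(tables)[-1L]) {
    idi <- rownames(tables[[i]]$values)
    missing_here <- setdiff(ids, idi)
    extra_here <- setdiff(idi, ids)
    bad <- union(missing_here, extra_here)
    if (length(bad)) {
      stop("samples not present in every block: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  vals <- do.call(cbind, lapply(tables, function(t) {
    t$values[ids, , drop = FALSE]
  }))
  if (anyDuplicated(colnames(vals))) {
    stop("variable names must be unique across blocks", call. = FALSE)
  }
  blocks <- do.call(c, lapply(tables, `[[`, "blocks"))
  g1 <- tables[[1L]]$groups
  for (i in seq_along(tables)[-1L]) {
    gi <- tables[[i]]$groups[match(ids, rownames(tables[[i]]$values))]
    if (!all(as.character(gi) == as.character(g1))) {
      stop("group labels disagree across blocks", call. = FALSE)
    }
  }
  metabolite_table(vals, g1, blocks)
}
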