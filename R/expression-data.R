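#' Expression dataset
#'
#' Container for a genes x patterns matrix of expression log-ratios (positive =
#' over-expressed relative to the reference condition, negative =
#' under-expressed). In `steady_state` mode each column is an independent
#' experiment and a target gene's value is read from the same column as its
#' regulators' values. In `time_series` mode each column is a transition: the
#' `values` matrix holds the expression profile at time t and `target_values`
#' the profile at time t + 1, so that pattern mu pairs regulator inputs at t
#' with the target at t + 1.
#'
#' @param values numeric matrix, rows = genes, columns = patterns. `NA`
#'   entries are treated as missing.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param mode `"steady_state"` or `"time_series"`.
#' @param target_values numeric matrix of the same shape as `values` holding
#'   the time t + 1 profiles; required in `time_series` mode.
#' @param missing_mask logical matrix marking missing entries; defaults to
#'   `is.na(values)`.
#' @return An object of class `expression_dataset`.
#' @seealso [pair_timepoints()] to turn an ordered time course into
#'   transitions, [read_expression_tsv()] for file input.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               mode = c("steady_state", "time_series"),
                               target_values = NULL,
                               missing_mask = is.na(values)) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) [", length(gene_ids), "] != nrow(values) [",
         nrow(values), "]")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "))
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stop("'missing_mask' and 'values' must have identical dimensions")
  if (mode == "time_series") {
    if (is.null(target_values))
      stop("time_series mode requires 'target_values'")
    target_values <- as.matrix(target_values)
    if (!identical(dim(target_values), dim(values)))
      stop("'target_values' and 'values' must have identical dimensions")
    rownames(target_values) <- gene_ids
  }
  rownames(values) <- gene_ids
  rownames(missing_mask) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids, mode = mode,
                 target_values = target_values, missing_mask = missing_mask),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d patterns (%s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  nmiss <- sum(x$missing_mask)
  if (nmiss > 0) cat(sprintf("  %d missing entries\n", nmiss))
  invisible(x)
}

#' Number of genes / patterns in a dataset
#' @param data an [expression_dataset()].
#' @return integer count.
#' @export
n_genes <- function(data) nrow(data$values)

#' @rdname n_genes
#' @export
n_patterns <- function(data) ncol(data$values)

#' Pair consecutive time points into transitions
#'
#' Converts an ordered time-course matrix (columns = time points) into a
#' `time_series` dataset of M - 1 transition patterns per series, pairing
#' column t (inputs) with column t + 1 (targets). With a `series` factor,
#' pairs are formed only within consecutive columns of the same series, so
#' several independent trajectories can share one matrix.
#'
#' @param data an [expression_dataset()] whose columns are time-ordered.
#' @param series optional vector (length = number of columns) labelling the
#'   trajectory each column belongs to.
#' @return a `time_series` [expression_dataset()] of transitions.
#' @export
pair_timepoints <- function(data, series = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  M <- ncol(data$values)
  if (M < 2) stop("need at least two time points to form a transition")
  if (is.null(series)) series <- rep(1L, M)
  if (length(series) != M) stop("'series' must have one entry per column")
  keep <- which(series[-M] == series[-1])
  if (!length(keep)) stop("no consecutive pair shares a series label")
  expression_dataset(values = data$values[, keep, drop = FALSE],
                     gene_ids = data$gene_ids,
                     mode = "time_series",
                     target_values = data$values[, keep + 1L, drop = FALSE],
                     missing_mask = data$missing_mask[, keep, drop = FALSE])
}

#' Default candidate regulators for a target
#'
#' In `steady_state` mode the target itself is excluded (its value in a
#' pattern is the quantity being explained). In `time_series` mode the
#' target's own profile at time t is a legitimate lagged input and is kept;
#' self-pairs are still never reported as regulatory links downstream.
#'
#' @param data an [expression_dataset()].
#' @param target gene identifier of the target.
#' @return character vector of candidate gene identifiers.
#' @export
default_candidates <- function(data, target) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!target %in% data$gene_ids) stop("unknown target gene: ", target)
  if (data$mode == "time_series") data$gene_ids
  else setdiff(data$gene_ids, target)
}

#' Build the single-target inference subproblem
#'
#' Extracts, for one target gene, the regulator input matrix and the target
#' sign vector used by the cost functions and the belief-propagation engine.
#' Missing regulator inputs are imputed as 0 (the reference level contributes
#' nothing to the local field); patterns whose target value is missing or has
#' zero log-ratio (no sign information) are dropped.
#'
#' @param data an [expression_dataset()].
#' @param target gene identifier of the target gene.
#' @param candidates character vector of candidate regulator identifiers;
#'   defaults to [default_candidates()].
#' @param include_bias if `TRUE`, append a constant input (id `".bias"`) whose
#'   coupling acts as an inferable ternary activation threshold.
#' @return An object of class `bp_problem`: list with `x` (regulators x
#'   usable patterns input matrix), `x0` (raw target values), `x0hat` (their
#'   signs), `regulators`, `target`, `pattern_index`.
#' @export
bp_problem <- function(data, target, candidates = NULL, include_bias = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!target %in% data$gene_ids) stop("unknown target gene: ", target)
  if (is.null(candidates)) candidates <- default_candidates(data, target)
  bad <- setdiff(candidates, data$gene_ids)
  if (length(bad))
    stop("unknown candidate gene(s): ", paste(bad, collapse = ", "))
  if (data$mode == "steady_state" && target %in% candidates)
    stop("steady-state candidates must not contain the target (", target, ")")
  tmat <- if (data$mode == "time_series") data$target_values else data$values
  y <- tmat[target, ]
  usable <- !is.na(y) & abs(y) > .Machine$double.eps
  if (!any(usable))
    stop("no usable pattern for target ", target,
         " (all target values missing or zero)")
  x <- data$values[candidates, usable, drop = FALSE]
  x[is.na(x)] <- 0
  if (include_bias) x <- rbind(x, ".bias" = 1)
  structure(list(x = x, x0 = y[usable], x0hat = sign(y[usable]),
                 regulators = rownames(x), target = target,
                 pattern_index = which(usable)),
            class = "bp_problem")
}

#' @export
print.bp_problem <- function(x, ...) {
  cat(sprintf("bp_problem: target '%s', %d candidate regulators, %d patterns\n",
              x$target, nrow(x$x), ncol(x$x)))
  invisible(x)
}
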