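## File dialects. Expression matrices are tab-separated text: a header row of
## experiment labels, then one row per gene whose first column is the gene
## identifier; an empty cell or "NA" marks a missing value. Transition
## (time-series) datasets use the same layout with paired columns <label>.in
## and <label>.out. Edge lists are TSV with columns regulator_id, target_id,
## sign, confidence (6 decimals). SIF uses "activates"/"represses" relations.

#' Read an expression matrix from TSV
#'
#' @param path file path.
#' @param mode dataset mode to stamp on the result. `"time_series"` expects
#'   the paired `.in`/`.out` column dialect written by
#'   [write_transitions_tsv()].
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(path, mode = c("steady_state", "time_series")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expected a header row and at least one gene row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol_expected <- length(header) + 1L   # gene id column + experiments
  widths <- lengths(cells[-1])
  ragged <- which(widths != ncol_expected)
  if (length(ragged))
    stop("ragged row(s) at line(s) ", paste(ragged + 1L, collapse = ", "),
         ": expected ", ncol_expected, " fields")
  ids <- vapply(cells[-1], `[[`, character(1), 1L)
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate gene id(s) at line(s) ", paste(dup + 1L, collapse = ", "),
         ": ", paste(unique(ids[dup]), collapse = ", "))
  parse_row <- function(cl) {
    v <- cl[-1]
    v[v == "NA" | v == ""] <- NA
    as.numeric(v)
  }
  vals <- do.call(rbind, lapply(cells[-1], parse_row))
  rownames(vals) <- ids
  colnames(vals) <- header
  if (mode == "time_series") {
    is_in <- grepl("\\.in$", header)
    is_out <- grepl("\\.out$", header)
    if (!any(is_in) || sum(is_in) != sum(is_out))
      stop("time_series TSV needs paired '<label>.in' / '<label>.out' columns")
    lab_in <- sub("\\.in$", "", header[is_in])
    lab_out <- sub("\\.out$", "", header[is_out])
    if (!identical(sort(lab_in), sort(lab_out)))
      stop("mismatched .in/.out column labels")
    vin <- vals[, is_in, drop = FALSE]
    vout <- vals[, is_out, drop = FALSE][, match(lab_in, lab_out),
                                         drop = FALSE]
    colnames(vin) <- colnames(vout) <- lab_in
    expression_dataset(vin, gene_ids = ids, mode = "time_series",
                       target_values = vout)
  } else {
    expression_dataset(vals, gene_ids = ids, mode = "steady_state")
  }
}

fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  out
}

#' Write an expression matrix to TSV
#'
#' Finite values round-trip bit-exactly through [read_expression_tsv()].
#'
#' @param data an [expression_dataset()] (steady-state; for transitions use
#'   [write_transitions_tsv()]).
#' @param path output file path.
#' @export
write_expression_tsv <- function(data, path) {
  stopifnot(inherits(data, "expression_dataset"))
  v <- data$values
  v[data$missing_mask] <- NA
  cn <- colnames(v)
  if (is.null(cn)) cn <- paste0("e", seq_len(ncol(v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cn, collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(data$gene_ids[i], fmt_num(v[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
write_transitions_tsv <- function(data, path) {
  stopifnot(inherits(data, "expression_dataset"))
  if (data$mode != "time_series")
    stop("write_transitions_tsv needs a time_series dataset")
  labs <- colnames(data$values)
  if (is.null(labs)) labs <- paste0("p", seq_len(ncol(data$values)))
  v <- cbind(data$values, data$target_values)
  colnames(v) <- c(paste0(labs, ".in"), paste0(labs, ".out"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(v), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(data$gene_ids[i], fmt_num(v[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' Variance and missing-data gene filter
#'
#' Drops genes showing little differential expression (variance smaller than
#' `min_var_factor` times the minimal gene variance measured in the dataset)
#' or with more than `max_missing` missing entries. Variances use the
#' unbiased (n - 1) denominator over non-missing entries, and the minimal
#' variance is measured before any removal; the reference value is carried
#' on the result (attribute `min_var_reference`) so that filtering is
#' idempotent.
#'
#' @param data an [expression_dataset()] with >= 2 patterns.
#' @param min_var_factor variance threshold multiplier.
#' @param max_missing maximum tolerated missing entries per gene.
#' @param min_var explicit variance reference overriding the measured
#'   minimum (used internally for idempotence).
#' @return the filtered [expression_dataset()], with attributes
#'   `removal_log` (data.frame `gene`, `reason`) and `min_var_reference`.
#' @export
filter_genes <- function(data, min_var_factor = 3, max_missing = 10,
                         min_var = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  if (ncol(data$values) < 2) stop("need >= 2 patterns to estimate variances")
  v <- apply(data$values, 1, stats::var, na.rm = TRUE)
  nmiss <- rowSums(data$missing_mask)
  if (is.null(min_var)) min_var <- attr(data, "min_var_reference")
  if (is.null(min_var)) min_var <- min(v, na.rm = TRUE)
  low_var <- !is.na(v) & v < min_var_factor * min_var
  too_missing <- nmiss > max_missing
  drop <- low_var | too_missing | is.na(v)
  if (all(drop)) stop("all genes removed by the filter")
  reason <- ifelse(too_missing, "missing",
                   ifelse(low_var | is.na(v), "low_variance", ""))
  log <- data.frame(gene = data$gene_ids[drop], reason = reason[drop],
                    stringsAsFactors = FALSE)
  keep <- which(!drop)
  out <- expression_dataset(
    values = data$values[keep, , drop = FALSE],
    gene_ids = data$gene_ids[keep], mode = data$mode,
    target_values = if (is.null(data$target_values)) NULL else
      data$target_values[keep, , drop = FALSE],
    missing_mask = data$missing_mask[keep, , drop = FALSE])
  attr(out, "removal_log") <- log
  attr(out, "min_var_reference") <- min_var
  out
}

#' Write / read an edge list
#'
#' @param network an `inferred_network` or link data.frame.
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  links <- if (inherits(network, "inferred_network")) network$links else network
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("regulator_id\ttarget_id\tsign\tconfidence", con)
  if (nrow(links))
    writeLines(sprintf("%s\t%s\t%+d\t%.6f", links$regulator, links$target,
                       links$sign, links$confidence), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- c("regulator", "target", "sign", "confidence")[seq_along(df)]
  df
}

#' @rdname write_edge_list
#' @export
write_sif <- function(network, path) {
  links <- if (inherits(network, "inferred_network")) network$links else network
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(links))
    writeLines(sprintf("%s\t%s\t%s", links$regulator,
                       ifelse(links$sign > 0, "activates", "represses"),
                       links$target), con)
  invisible(path)
}

#' Run metadata sidecar
#'
#' Writes (or reads) the JSON sidecar recording the parameters a network was
#' inferred with, sufficient to reproduce the run.
#'
#' @param network an `inferred_network`.
#' @param path file path (conventionally `<edges>.json`).
#' @export
write_run_sidecar <- function(network, path) {
  stopifnot(inherits(network, "inferred_network"))
  meta <- network$params
  meta$h_final <- network$h
  meta$n_links <- nrow(network$links)
  meta$n_sign_ties <- network$n_sign_ties
  meta$per_target <- network$per_target
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_sidecar
#' @export
read_run_sidecar <- function(path) jsonlite::read_json(path)

#' Read a plain-text gene list (one identifier per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !grepl("^#", x)]
}
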