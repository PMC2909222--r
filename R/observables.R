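#' Deterministically rank a link table
#'
#' Orders links by descending confidence; exact ties are broken by the
#' position of the regulator, then the target, in `gene_order` (so rankings
#' are reproducible).
#'
#' @param links data.frame with columns `regulator`, `target`, `sign`,
#'   `confidence` (or an `inferred_network`, whose unthresholded link table
#'   is used).
#' @param gene_order character vector fixing the tie-break order; defaults
#'   to the sorted union of identifiers in the table.
#' @return the ranked data.frame.
#' @export
rank_links <- function(links, gene_order = NULL) {
  if (inherits(links, "inferred_network")) {
    if (is.null(gene_order)) gene_order <- links$gene_ids
    links <- links$all_links
  }
  stopifnot(all(c("regulator", "target", "confidence") %in% names(links)))
  if (is.null(gene_order))
    gene_order <- sort(unique(c(links$regulator, links$target)))
  o <- order(-links$confidence,
             match(links$regulator, gene_order),
             match(links$target, gene_order))
  out <- links[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

match_truth <- function(ranked, truth, require_sign = TRUE) {
  if (is.null(truth) || nrow(truth) == 0) stop("empty truth edge set")
  key <- function(df) paste(df$regulator, df$target, sep = "\r")
  hit <- key(ranked) %in% key(truth)
  if (require_sign) {
    skey <- function(df) paste(df$regulator, df$target, df$sign, sep = "\r")
    hit <- skey(ranked) %in% skey(truth)
  }
  hit
}

#' Precision-recall curve of a ranked link list
#'
#' At each rank cutoff k, counts predictions present in the gold-standard
#' edge set (with matching sign unless `require_sign = FALSE`) as true
#' positives and computes precision N_TP / (N_TP + N_FP) and recall
#' N_TP / (N_TP + N_FN).
#'
#' @param ranked ranked link data.frame (see [rank_links()]) or an
#'   `inferred_network`.
#' @param truth data.frame with columns `regulator`, `target`, `sign`.
#' @param require_sign require sign agreement for a true positive.
#' @return object of class `pr_curve`: data.frame with columns `k`, `n_tp`,
#'   `n_fp`, `n_fn`, `precision`, `recall`.
#' @export
precision_recall <- function(ranked, truth, require_sign = TRUE) {
  if (inherits(ranked, "inferred_network")) ranked <- rank_links(ranked)
  hit <- match_truth(ranked, truth, require_sign)
  tp <- cumsum(hit)
  k <- seq_along(hit)
  fp <- k - tp
  fn <- nrow(truth) - tp
  out <- data.frame(k = k, n_tp = tp, n_fp = fp, n_fn = fn,
                    precision = ifelse(k > 0, tp / k, NA_real_),
                    recall = tp / nrow(truth))
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Length of the error-free prefix of a ranking
#'
#' Number of correctly predicted links before the first error, i.e. the
#' largest k at which the precision is still 1.
#'
#' @inheritParams precision_recall
#' @return integer >= 0.
#' @export
links_before_first_error <- function(ranked, truth, require_sign = TRUE) {
  if (inherits(ranked, "inferred_network")) ranked <- rank_links(ranked)
  if (nrow(ranked) == 0) return(0L)
  hit <- match_truth(ranked, truth, require_sign)
  miss <- which(!hit)
  if (!length(miss)) length(hit) else miss[1] - 1L
}

#' Pearson co-expression baseline network
#'
#' Ranks candidate -> target pairs by the absolute Pearson correlation of
#' their expression profiles (pairwise-complete over non-missing patterns),
#' with the link sign given by the correlation sign. For time-series data
#' the candidate profile at time t is correlated with the target at t + 1.
#' Pairs with fewer than `min_obs` complete observations or an undefined
#' correlation (constant profile) are skipped with a notice.
#'
#' @param data an [expression_dataset()].
#' @param candidates,targets gene identifier vectors (defaults: all genes,
#'   excluding self-pairs).
#' @param n_links truncate the ranking to this many links (`NULL` = all).
#' @param min_obs minimum complete pattern pairs per gene pair.
#' @return ranked link data.frame (`regulator`, `target`, `sign`,
#'   `confidence` = |r|).
#' @export
pearson_baseline <- function(data, candidates = NULL, targets = NULL,
                             n_links = NULL, min_obs = 3) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(candidates)) candidates <- data$gene_ids
  if (is.null(targets)) targets <- data$gene_ids
  bad <- setdiff(c(candidates, targets), data$gene_ids)
  if (length(bad)) stop("unknown gene(s): ", paste(unique(bad), collapse = ", "))
  tmat <- if (data$mode == "time_series") data$target_values else data$values
  rows <- list()
  n_skipped <- 0L
  for (tg in targets) {
    y <- tmat[tg, ]
    for (cd in candidates) {
      if (cd == tg) next
      xx <- data$values[cd, ]
      ok <- !is.na(xx) & !is.na(y)
      if (sum(ok) < min_obs) { n_skipped <- n_skipped + 1L; next }
      r <- suppressWarnings(stats::cor(xx[ok], y[ok]))
      if (is.na(r)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <-
        data.frame(regulator = cd, target = tg,
                   sign = if (r >= 0) 1L else -1L,
                   confidence = abs(r), stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0)
    message(n_skipped, " gene pair(s) skipped (too few complete patterns ",
            "or constant profile)")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(regulator = character(0), target = character(0),
               sign = integer(0), confidence = numeric(0))
  out <- rank_links(out, gene_order = data$gene_ids)
  if (!is.null(n_links)) out <- utils::head(out, n_links)
  out
}

#' Statistical independence of co-regulators
#'
#' For every unordered pair of regulators sharing at least one target in the
#' network, computes 1 - |Pearson correlation| of their expression profiles:
#' values near 1 mean the two regulators carry independent information about
#' their common target, values near 0 that they are redundant.
#'
#' @param network an `inferred_network` or a link data.frame.
#' @param data the [expression_dataset()] the profiles are read from.
#' @return numeric vector (one value per co-regulating pair), empty with a
#'   notice when no target has two or more regulators.
#' @export
regulator_independence <- function(network, data) {
  links <- if (inherits(network, "inferred_network")) network$links else network
  stopifnot(inherits(data, "expression_dataset"))
  pairs <- list()
  for (tg in unique(links$target)) {
    regs <- sort(unique(links$regulator[links$target == tg]))
    if (length(regs) < 2) next
    cmb <- utils::combn(regs, 2)
    for (j in seq_len(ncol(cmb)))
      pairs[[paste(cmb[, j], collapse = "\r")]] <- cmb[, j]
  }
  if (!length(pairs)) {
    message("no target with two or more regulators; empty distribution")
    return(numeric(0))
  }
  vapply(pairs, function(pr) {
    a <- data$values[pr[1], ]; b <- data$values[pr[2], ]
    ok <- !is.na(a) & !is.na(b)
    r <- suppressWarnings(stats::cor(a[ok], b[ok]))
    if (is.na(r)) NA_real_ else 1 - abs(r)
  }, numeric(1), USE.NAMES = FALSE)
}

#' In-degree statistics of an inferred network
#'
#' @param network an `inferred_network` or link data.frame.
#' @param targets the target universe (so targets without any predicted
#'   regulator are counted); defaults to the targets present in the links.
#' @return list with `in_degree` (named integer vector over `targets`),
#'   `mean_per_target`, `mean_per_regulated` (mean over targets with at
#'   least one regulator), `n_unregulated`, and `gamma`, the maximum-
#'   likelihood rate of an exponential fit to the in-degrees of regulated
#'   targets (gamma = 1 / mean degree).
#' @export
degree_stats <- function(network, targets = NULL) {
  links <- if (inherits(network, "inferred_network")) network$links else network
  if (nrow(links) == 0) stop("empty network")
  if (is.null(targets)) targets <- sort(unique(links$target))
  k <- vapply(targets, function(tg) sum(links$target == tg), integer(1))
  reg <- k[k > 0]
  list(in_degree = k,
       mean_per_target = mean(k),
       mean_per_regulated = mean(reg),
       n_unregulated = sum(k == 0),
       gamma = 1 / mean(reg))
}

#' Overlap with a reference network against an in-degree-preserving null
#'
#' Counts directed edges shared between `network` and `reference`, then
#' compares the count with a null ensemble in which each target keeps its
#' number of regulators but the regulators are redrawn uniformly without
#' replacement from the candidate pool (self-loops forbidden). Reports the
#' z-score and the Gaussian upper-tail p-value (as well as the empirical
#' tail frequency).
#'
#' @param network an `inferred_network` or link data.frame.
#' @param reference data.frame of reference edges (`regulator`, `target`).
#' @param candidate_pool regulator identifiers to redraw from; defaults to
#'   the regulators appearing in `network`.
#' @param n_scrambles null-model sample size (>= 100).
#' @param seed RNG seed.
#' @param require_sign overlap requires matching sign (only if both tables
#'   carry signs).
#' @return list with `overlap`, `null_mean`, `null_sd`, `z`, `p_gauss`,
#'   `p_empirical`. With a degenerate null (sd = 0) `z` is `NA`.
#' @export
null_model_overlap <- function(network, reference, candidate_pool = NULL,
                               n_scrambles = 1000, seed = 1,
                               require_sign = FALSE) {
  links <- if (inherits(network, "inferred_network")) network$links else network
  if (n_scrambles < 100) stop("n_scrambles must be >= 100")
  if (is.null(reference) || nrow(reference) == 0) stop("empty reference")
  net_genes <- unique(c(links$regulator, links$target))
  if (!any(unique(c(reference$regulator, reference$target)) %in% net_genes))
    stop("reference and network share no gene identifiers")
  if (is.null(candidate_pool)) candidate_pool <- unique(links$regulator)
  ov <- function(df) {
    if (require_sign)
      sum(paste(df$regulator, df$target, df$sign) %in%
            paste(reference$regulator, reference$target, reference$sign))
    else
      sum(paste(df$regulator, df$target) %in%
            paste(reference$regulator, reference$target))
  }
  observed <- ov(links)
  set.seed(seed)
  tg_counts <- table(links$target)
  null_ov <- vapply(seq_len(n_scrambles), function(s) {
    rows <- lapply(names(tg_counts), function(tg) {
      pool <- setdiff(candidate_pool, tg)
      kk <- min(tg_counts[[tg]], length(pool))
      data.frame(regulator = sample(pool, kk), target = tg,
                 sign = sample(c(-1L, 1L), kk, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    ov(do.call(rbind, rows))
  }, numeric(1))
  m <- mean(null_ov); sdev <- stats::sd(null_ov)
  z <- if (sdev > 0) (observed - m) / sdev else NA_real_
  list(overlap = observed, null_mean = m, null_sd = sdev, z = z,
       p_gauss = if (is.na(z)) NA_real_ else
         stats::pnorm(z, lower.tail = FALSE),
       p_empirical = mean(null_ov >= observed))
}
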