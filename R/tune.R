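## Diluting-field cooling. The field h is conjugate to the number of
## effective links, so either can be fixed: the cooling loop interleaves one
## multiplicative h update with every BP sweep (raising h when the expected
## N_eff is above target, lowering it when below), which also keeps BP away
## from frozen overconfident fixed points on hard instances. Once the target
## is bracketed, h is frozen, messages are run to convergence, and a short
## bisection refines h. The zero-entropy mode instead ramps h upward until
## the Bethe entropy first crosses zero.

#' Tune the diluting field
#'
#' Adjusts h over one or several single-target subproblems (one global h
#' shared across all of them) until either the summed expected number of
#' effective links reaches a target, or the summed Bethe entropy first drops
#' to zero.
#'
#' @param problems a single [bp_problem()] or a list of them.
#' @param params a [model_params()]; its `h` is the starting value of the
#'   cooling (0 is replaced by 1).
#' @param mode `"n_eff"` or `"zero_entropy"`.
#' @param n_eff_target desired summed E\[N_eff\] (required for `"n_eff"`).
#' @param seed seed for message initialization.
#' @param eps multiplicative cooling step: h <- h * (1 +/- eps).
#' @param damping damping factor for the BP sweeps.
#' @param cool_sweeps cap on interleaved cooling sweeps.
#' @param converge_iters cap on the post-freeze convergence run.
#' @param tol message-convergence threshold.
#' @param n_eff_tol acceptable |E\[N_eff\] - target| after refinement.
#' @param h_bounds admissible range for h; leaving it means the target is
#'   unreachable and is an error.
#' @return object of class `bp_tune`: list with `results` (one [bp_iterate()]
#'   result per problem), `h` (final field), `expected_n_eff` (summed),
#'   `entropy` (summed, NA if any problem unconverged), `mode`, `converged`.
#' @export
tune_h <- function(problems, params, mode = c("n_eff", "zero_entropy"),
                   n_eff_target = NULL, seed = 1, eps = 0.05, damping = 0.5,
                   cool_sweeps = 600, converge_iters = 300, tol = 1e-8,
                   n_eff_tol = 1, h_bounds = c(1e-4, 1e4)) {
  mode <- match.arg(mode)
  if (inherits(problems, "bp_problem")) problems <- list(problems)
  stopifnot(inherits(params, "model_params"))
  if (mode == "n_eff" && is.null(n_eff_target))
    stop("mode 'n_eff' requires n_eff_target")
  sigma <- params$sigma; tau <- params$tau
  h <- if (params$h > 0) params$h else 1
  msgs <- lapply(seq_along(problems), function(q)
    init_messages(nrow(problems[[q]]$x), ncol(problems[[q]]$x),
                  seed + q - 1L))

  sweep_all <- function(h) {
    neff <- 0; dmax <- 0
    for (q in seq_along(problems)) {
      sw <- bp_sweep(msgs[[q]], problems[[q]], sigma, h, tau, damping)
      msgs[[q]] <<- sw$messages
      dmax <- max(dmax, sw$delta)
      pm <- bp_marginals_from_rho(msgs[[q]]$rho, h)
      neff <- neff + sum(1 - pm[, 2])
    }
    list(neff = neff, dmax = dmax)
  }
  converge_all <- function(h) {
    res <- vector("list", length(problems))
    for (q in seq_along(problems)) {
      res[[q]] <- suppressWarnings(
        bp_iterate(problems[[q]], model_params(sigma, h, tau), seed = seed,
                   max_iter = converge_iters, tol = tol, damping = damping,
                   messages = msgs[[q]]))
      msgs[[q]] <<- res[[q]]$messages
    }
    res
  }
  total_neff <- function(res) sum(vapply(res, function(r) r$expected_n_eff,
                                         numeric(1)))

  if (mode == "n_eff") {
    above <- NA; flips <- 0L; step <- eps; at_bound <- FALSE
    for (sw in seq_len(cool_sweeps)) {
      st <- sweep_all(h)
      if (sw > 30 && st$dmax < tol &&
          abs(st$neff - n_eff_target) <= n_eff_tol) break
      now_above <- st$neff > n_eff_target
      if (!is.na(above) && now_above != above) {
        flips <- flips + 1L
        if (flips == 2L) step <- eps / 4   # bracketed: slow down
      }
      above <- now_above
      h <- if (now_above) h * (1 + step) else h / (1 + step)
      if (h < h_bounds[1] || h > h_bounds[2]) {
        h <- min(max(h, h_bounds[1]), h_bounds[2])
        at_bound <- TRUE
        break
      }
      if (sw > 60 && flips >= 2L && st$dmax < tol) break
    }
    res <- converge_all(h)
    if (at_bound && abs(total_neff(res) - n_eff_target) > n_eff_tol)
      stop("N_eff target ", n_eff_target, " unreachable within h bounds [",
           h_bounds[1], ", ", h_bounds[2], "]: E[N_eff] = ",
           signif(total_neff(res), 4), " at h = ", signif(h, 4))
    # bisection refinement on the converged E[N_eff](h), warm-started
    if (abs(total_neff(res) - n_eff_target) > n_eff_tol) {
      lo <- h / (1 + 4 * eps); hi <- h * (1 + 4 * eps)
      for (k in 1:12) {
        mid <- sqrt(lo * hi)
        res <- converge_all(mid)
        if (total_neff(res) > n_eff_target) lo <- mid else hi <- mid
        h <- mid
        if (abs(total_neff(res) - n_eff_target) <= n_eff_tol) break
      }
    }
  } else {
    # zero-entropy cooling: ramp h up from its start until S <= 0
    repeat {
      res <- converge_all(h)
      S <- sum(vapply(seq_along(res), function(q) {
        if (!res[[q]]$converged) return(NA_real_)
        res[[q]]$entropy
      }, numeric(1)))
      if (!is.na(S) && S <= 0) break
      h <- h * (1 + eps)
      if (h > h_bounds[2])
        stop("entropy never crossed zero within h bounds (h reached ",
             signif(h, 4), ")")
    }
  }
  conv <- all(vapply(res, function(r) r$converged, logical(1)))
  ent <- if (conv) sum(vapply(res, function(r) r$entropy, numeric(1)))
         else NA_real_
  structure(list(results = res, h = h, expected_n_eff = total_neff(res),
                 entropy = ent, mode = mode, converged = conv),
            class = "bp_tune")
}

#' @export
print.bp_tune <- function(x, ...) {
  cat(sprintf("bp_tune (%s): h = %.4g, E[N_eff] = %.2f, entropy = %.4g, %s\n",
              x$mode, x$h, x$expected_n_eff, x$entropy,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Infer a regulatory network
#'
#' Runs the per-target belief-propagation pipeline over a set of target
#' genes (the inference factorizes over targets) and assembles the directed,
#' signed edge list. Each candidate coupling contributes a confidence
#' 1 - P_i(J = 0); the edge sign is the more probable nonzero state. An
#' exact sign tie makes no prediction and the edge is excluded (counted in
#' attribute `n_sign_ties`). Self-pairs (a gene's lagged profile explaining
#' itself in time-series mode) are never reported as links.
#'
#' @param data an [expression_dataset()].
#' @param params a [model_params()]; `sigma` and `tau` are used, and `h` is
#'   the fixed field when `h_mode = "fixed"` or the cooling start otherwise.
#' @param targets target gene identifiers (default: all genes).
#' @param candidates candidate regulator identifiers (default:
#'   [default_candidates()] per target).
#' @param h_mode `"global"` (one field cooled so the summed E\[N_eff\] over
#'   all targets reaches `n_eff_target`), `"per_target"` (one field per
#'   target), or `"fixed"` (use `params$h` as is).
#' @param n_eff_target target for the cooling (summed over targets for
#'   `"global"`, per target for `"per_target"`).
#' @param confidence_threshold keep links with confidence strictly above
#'   this value (1.0 keeps nothing).
#' @param seed master seed for message initialization.
#' @param include_bias append a constant input per target whose coupling
#'   acts as an inferable activation threshold (never reported as a link).
#' @param ... passed on to [tune_h()].
#' @return object of class `inferred_network`: a list with `links` (a
#'   data.frame `regulator`, `target`, `sign`, `confidence`, sorted by
#'   descending confidence with ties broken by gene order), `all_links`
#'   (same, unthresholded), `h`, `params`, `per_target` diagnostics.
#' @export
infer_network <- function(data, params, targets = NULL, candidates = NULL,
                          h_mode = c("global", "per_target", "fixed"),
                          n_eff_target = NULL,
                          confidence_threshold = 0.95, seed = 1,
                          include_bias = FALSE, ...) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(params, "model_params"))
  h_mode <- match.arg(h_mode)
  if (is.null(targets)) targets <- data$gene_ids
  bad <- setdiff(targets, data$gene_ids)
  if (length(bad)) stop("unknown target gene(s): ", paste(bad, collapse = ", "))
  if (!is.null(candidates)) {
    bad <- setdiff(candidates, data$gene_ids)
    if (length(bad))
      stop("unknown candidate gene(s): ", paste(bad, collapse = ", "))
  }
  probs <- lapply(targets, function(tg) {
    cand <- if (is.null(candidates)) default_candidates(data, tg)
            else setdiff(candidates, if (data$mode == "steady_state") tg
                         else character(0))
    bp_problem(data, tg, cand, include_bias = include_bias)
  })
  if (h_mode == "global") {
    tn <- tune_h(probs, params, mode = "n_eff", n_eff_target = n_eff_target,
                 seed = seed, ...)
    results <- tn$results
    h_final <- tn$h
  } else if (h_mode == "per_target") {
    results <- vector("list", length(probs))
    h_final <- numeric(length(probs))
    for (q in seq_along(probs)) {
      tn <- tune_h(probs[[q]], params, mode = "n_eff",
                   n_eff_target = n_eff_target, seed = seed + 1000L * q, ...)
      results[[q]] <- tn$results[[1]]
      h_final[q] <- tn$h
    }
  } else {
    results <- lapply(seq_along(probs), function(q)
      bp_iterate(probs[[q]], params, seed = seed + 1000L * q, ...))
    h_final <- params$h
  }
  rows <- list()
  n_ties <- 0L
  for (q in seq_along(results)) {
    r <- results[[q]]
    for (k in seq_along(r$regulators)) {
      reg <- r$regulators[k]
      if (reg == r$target || reg == ".bias") next
      pm <- r$marginals[k, ]
      if (pm[3] == pm[1]) { n_ties <- n_ties + 1L; next }
      rows[[length(rows) + 1L]] <-
        data.frame(regulator = reg, target = r$target,
                   sign = if (pm[3] > pm[1]) 1L else -1L,
                   confidence = 1 - pm[2], stringsAsFactors = FALSE)
    }
  }
  all_links <- if (length(rows)) do.call(rbind, rows) else
    data.frame(regulator = character(0), target = character(0),
               sign = integer(0), confidence = numeric(0))
  all_links <- rank_links(all_links, gene_order = data$gene_ids)
  links <- all_links[all_links$confidence > confidence_threshold, ,
                     drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links, all_links = all_links, h = h_final,
                 params = list(sigma = params$sigma, tau = params$tau,
                               h = h_final, h_mode = h_mode,
                               n_eff_target = n_eff_target,
                               confidence_threshold = confidence_threshold,
                               seed = seed, mode = data$mode,
                               include_bias = include_bias),
                 per_target = lapply(results, function(r)
                   list(target = r$target, converged = r$converged,
                        iterations = r$iterations,
                        expected_n_eff = r$expected_n_eff)),
                 gene_ids = data$gene_ids, n_sign_ties = n_ties),
            class = "inferred_network")
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf("inferred_network: %d links above confidence %.3g (%d scored), h = %s\n",
              nrow(x$links), x$params$confidence_threshold,
              nrow(x$all_links),
              paste(signif(x$h, 4), collapse = ", ")))
  invisible(x)
}
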