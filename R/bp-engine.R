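## Belief propagation for ternary couplings on the dense pattern/coupling
## factor graph. Variables i are candidate couplings J_i in {-1,0,+1};
## factors mu are expression patterns. Messages are stored as N x M x 3
## arrays with the third dimension indexing J = -1, 0, +1. All updates are
## O(M N) per sweep via the subtraction trick: per-pattern totals are formed
## once and the single term of regulator i is removed.

J_STATES <- c(-1, 0, 1)
RHO_FLOOR <- 1e-300   # keeps logs finite when a state is strictly excluded

normalize3 <- function(arr) {
  z <- arr[, , 1] + arr[, , 2] + arr[, , 3]
  for (j in 1:3) arr[, , j] <- arr[, , j] / z
  arr
}

#' Randomly initialized message set
#'
#' Creates strictly positive, normalized factor-to-variable (`rho`) and
#' variable-to-factor (`p`) messages over the 3-state coupling alphabet,
#' deterministically from a seed.
#'
#' @param n_regulators number of variable nodes (candidate couplings).
#' @param n_patterns number of factor nodes (patterns).
#' @param seed RNG seed (reproducibility contract: identical seeds give
#'   identical messages).
#' @return object of class `message_set` with arrays `rho` and `p`
#'   (`n_regulators` x `n_patterns` x 3).
#' @export
init_messages <- function(n_regulators, n_patterns, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  rand3 <- function() {
    a <- array(stats::runif(n_regulators * n_patterns * 3, 0.5, 1.5),
               c(n_regulators, n_patterns, 3))
    if (n_patterns == 0) a else normalize3(a)
  }
  structure(list(rho = rand3(), p = rand3()), class = "message_set")
}

#' Cavity statistics of the local field
#'
#' For each (pattern mu, regulator i), the mean `t` and variance `delta2` of
#' the local field Lambda^mu excluding regulator i, under the product of
#' variable-to-factor messages; `full_t`/`full_delta2` are the per-pattern
#' totals over all regulators from which single terms are subtracted
#' (O(MN) total work).
#'
#' @param messages a `message_set` (its `p` array is used).
#' @param problem a [bp_problem()].
#' @return object of class `cavity_stats`: list with `t`, `delta2` (N x M),
#'   `full_t`, `full_delta2` (length M).
#' @export
update_cavity_stats <- function(messages, problem) {
  x <- problem$x
  p <- messages$p
  m1 <- p[, , 3] - p[, , 1]            # <J>
  m2 <- p[, , 3] + p[, , 1]            # <J^2>
  if (is.null(dim(m1))) { m1 <- matrix(m1, nrow = dim(p)[1]); m2 <- matrix(m2, nrow = dim(p)[1]) }
  v <- (m2 - m1^2) * x^2
  full_t <- colSums(m1 * x)
  full_delta2 <- colSums(v)
  t_cav <- sweep(-m1 * x, 2, full_t, "+")
  delta2 <- sweep(-v, 2, full_delta2, "+")
  delta2[delta2 < 0] <- 0              # guard tiny negative round-off
  structure(list(t = t_cav, delta2 = delta2,
                 full_t = full_t, full_delta2 = full_delta2,
                 m1 = m1, m2 = m2),
            class = "cavity_stats")
}

#' Factor-to-variable messages under the Gaussian approximation
#'
#' rho_{mu->i}(J) is proportional to
#' Phi( x0hat^mu (J x_i^mu + t_{mu->i} + tau) / sqrt(sigma^2 + Delta^2_{mu->i}) ):
#' the exhaustive sum over cavity couplings is replaced by a single Gaussian
#' integral over the cavity field (central-limit approximation), which is
#' exact under the probit likelihood. A vanishing denominator degenerates to
#' the tie-ruled step (1 / 0.5 / 0 for positive / zero / negative argument).
#'
#' @param cavity a [update_cavity_stats()] result.
#' @param problem a [bp_problem()].
#' @param sigma noise standard deviation (>= 0).
#' @param tau activation threshold.
#' @return normalized `rho` array (N x M x 3).
#' @export
update_factor_messages <- function(cavity, problem, sigma, tau = 0) {
  x <- problem$x
  N <- nrow(x); M <- ncol(x)
  den <- sqrt(sigma^2 + cavity$delta2)
  rho <- array(0, c(N, M, 3))
  for (j in 1:3) {
    arg <- sweep(J_STATES[j] * x + cavity$t + tau, 2, problem$x0hat, "*")
    v <- ifelse(den > 0, stats::pnorm(arg / pmax(den, 1e-300)),
                ifelse(arg > 0, 1, ifelse(arg < 0, 0, 0.5)))
    rho[, , j] <- pmax(v, RHO_FLOOR)
  }
  normalize3(rho)
}

#' Variable-to-factor messages
#'
#' P_{i->mu}(J) is proportional to exp(-h 1[J != 0]) times the product of
#' rho_{nu->i}(J) over nu != mu, computed in log space from per-regulator
#' totals minus the single excluded factor (O(MN)).
#'
#' @param rho factor-to-variable message array (N x M x 3).
#' @param h diluting field (>= 0).
#' @return normalized `p` array of the same shape.
#' @export
update_variable_messages <- function(rho, h) {
  N <- dim(rho)[1]; M <- dim(rho)[2]
  pen <- c(h, 0, h)
  lr <- log(rho)
  p <- array(0, c(N, M, 3))
  if (M == 0) return(p)
  L <- apply(lr, c(1, 3), sum)                 # N x 3 totals
  if (is.null(dim(L))) L <- matrix(L, nrow = N)
  lp <- array(0, c(N, M, 3))
  for (j in 1:3) lp[, , j] <- L[, j] - lr[, , j] - pen[j]
  mx <- pmax(lp[, , 1], lp[, , 2], lp[, , 3])
  for (j in 1:3) p[, , j] <- exp(lp[, , j] - mx)
  normalize3(p)
}

bp_marginals_from_rho <- function(rho, h) {
  N <- dim(rho)[1]
  pen <- c(h, 0, h)
  L <- if (dim(rho)[2] == 0) matrix(0, N, 3) else apply(log(rho), c(1, 3), sum)
  if (is.null(dim(L))) L <- matrix(L, nrow = N)
  lm <- sweep(L, 2, pen)
  mx <- apply(lm, 1, max)
  pm <- exp(lm - mx)
  pm <- pm / rowSums(pm)
  colnames(pm) <- c("-1", "0", "+1")
  pm
}

bp_sweep <- function(messages, problem, sigma, h, tau = 0, damping = 0) {
  cav <- update_cavity_stats(messages, problem)
  rho_new <- update_factor_messages(cav, problem, sigma, tau)
  if (damping > 0) rho_new <- damping * messages$rho + (1 - damping) * rho_new
  delta <- max(abs(rho_new - messages$rho))
  p_new <- update_variable_messages(rho_new, h)
  messages$rho <- rho_new
  messages$p <- p_new
  list(messages = messages, delta = delta)
}

#' Run belief propagation to convergence for one target
#'
#' Iterates cavity -> factor -> variable message updates at fixed parameters
#' until the largest absolute message change drops below `tol` or `max_iter`
#' sweeps have run. Oscillation is detected (no improvement of the message
#' change over 30 sweeps) and answered by raising the damping factor to 0.5
#' (then 0.8) before giving up. Non-convergence is reported honestly via the
#' `converged` flag and a warning, never silently.
#'
#' @param problem a [bp_problem()].
#' @param params a [model_params()] (sigma, h, tau).
#' @param seed seed for the random message initialization.
#' @param max_iter sweep cap.
#' @param tol convergence threshold on the message change.
#' @param damping initial damping factor in `[0, 1)` on factor messages.
#' @param messages optional warm-start `message_set`.
#' @return object of class `bp_result`: `marginals` (N x 3), `confidence`
#'   (1 - P_i(0)), `converged`, `iterations`, `entropy` (Bethe entropy, NA
#'   if not converged), `expected_n_eff`, `h`, `sigma`, `messages`,
#'   `regulators`, `target`.
#' @export
bp_iterate <- function(problem, params, seed = 1, max_iter = 500,
                       tol = 1e-8, damping = 0, messages = NULL) {
  stopifnot(inherits(problem, "bp_problem"), inherits(params, "model_params"))
  N <- nrow(problem$x); M <- ncol(problem$x)
  if (is.null(messages)) messages <- init_messages(N, M, seed)
  if (M == 0) {
    pm <- bp_marginals_from_rho(array(1 / 3, c(N, 0, 3)), params$h)
    rownames(pm) <- problem$regulators
    return(structure(list(marginals = pm, confidence = 1 - pm[, 2],
                          converged = TRUE, iterations = 0L,
                          entropy = N * prior_site_entropy(params$h),
                          expected_n_eff = sum(1 - pm[, 2]),
                          h = params$h, sigma = params$sigma,
                          messages = messages,
                          regulators = problem$regulators,
                          target = problem$target),
                     class = "bp_result"))
  }
  best <- Inf; stall <- 0L; it <- 0L; delta <- Inf
  for (it in seq_len(max_iter)) {
    sw <- bp_sweep(messages, problem, params$sigma, params$h, params$tau,
                   damping)
    messages <- sw$messages
    delta <- sw$delta
    if (delta < tol) break
    if (delta < best * 0.999) { best <- delta; stall <- 0L } else stall <- stall + 1L
    if (stall >= 30L) {
      damping <- if (damping < 0.5) 0.5 else if (damping < 0.8) 0.8 else damping
      best <- delta; stall <- 0L
    }
  }
  converged <- delta < tol
  if (!converged)
    warning("BP did not converge for target '", problem$target,
            "' (last message change ", signif(delta, 3), ")")
  pm <- bp_marginals_from_rho(messages$rho, params$h)
  rownames(pm) <- problem$regulators
  res <- structure(list(marginals = pm, confidence = 1 - pm[, 2],
                        converged = converged, iterations = it,
                        entropy = NA_real_,
                        expected_n_eff = sum(1 - pm[, 2]),
                        h = params$h, sigma = params$sigma,
                        messages = messages,
                        regulators = problem$regulators,
                        target = problem$target),
                   class = "bp_result")
  if (converged)
    res$entropy <- bethe_entropy(res, problem, params)
  res
}

#' @export
print.bp_result <- function(x, ...) {
  cat(sprintf("bp_result: target '%s', %d regulators, %s after %d iterations\n",
              x$target, length(x$regulators),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  h = %.4g, sigma = %.4g, E[N_eff] = %.3f, entropy = %.4g\n",
              x$h, x$sigma, x$expected_n_eff, x$entropy))
  invisible(x)
}

prior_site_entropy <- function(h) {
  # entropy of the single-site prior P(0) = 1/(1+2e^-h), P(+/-1) = e^-h/(1+2e^-h)
  z <- 1 + 2 * exp(-h)
  p0 <- 1 / z
  p1 <- exp(-h) / z
  s <- 0
  if (p0 > 0) s <- s - p0 * log(p0)
  if (p1 > 0) s <- s - 2 * p1 * log(p1)
  s
}

gauss_hermite <- function(n) {
  # Golub-Welsch nodes/weights for integral of exp(-z^2) f(z) dz
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  Tm <- matrix(0, n, n)
  Tm[cbind(i, i + 1)] <- b
  Tm[cbind(i + 1, i)] <- b
  e <- eigen(Tm, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Bethe entropy of the coupling posterior
#'
#' Approximates the Shannon entropy of the posterior over coupling vectors -
#' the logarithm of the (weighted) number of high-scoring couplings - by the
#' Bethe expression on the pattern/coupling factor graph, evaluated from
#' converged messages. Factor contributions are computed under the Gaussian
#' cavity representation of the local field (the pattern-likelihood average
#' uses Gauss-Hermite quadrature). For M = 0 the entropy is N times the
#' entropy of the single-site prior. The cooling procedure stops at the
#' point where this entropy first crosses zero, i.e. where the solution set
#' becomes sub-exponential.
#'
#' @param result a converged [bp_iterate()] result (its messages are used).
#' @param problem the matching [bp_problem()].
#' @param params the matching [model_params()].
#' @param gh_points quadrature points for the factor average.
#' @return the Bethe entropy in nats (can be negative).
#' @export
bethe_entropy <- function(result, problem, params, gh_points = 31) {
  stopifnot(inherits(result, "bp_result"))
  if (!result$converged)
    stop("messages did not converge; re-run bp_iterate (more damping or ",
         "iterations) before computing the entropy")
  N <- nrow(problem$x); M <- ncol(problem$x)
  h <- params$h; sigma <- params$sigma
  if (M == 0) return(N * prior_site_entropy(h))
  msg <- result$messages
  rho <- msg$rho; p <- msg$p
  pen <- c(h, 0, h)
  # variable normalizers: Z_i = sum_J e^{-h1[J!=0]} prod_mu rho_mu->i(J)
  L <- apply(log(rho), c(1, 3), sum)
  if (is.null(dim(L))) L <- matrix(L, nrow = N)
  lm <- sweep(L, 2, pen)
  mx <- apply(lm, 1, max)
  log_zi <- log(rowSums(exp(lm - mx))) + mx
  # edge normalizers: Z_imu = sum_J p_i->mu(J) rho_mu->i(J)
  z_edge <- rho[, , 1] * p[, , 1] + rho[, , 2] * p[, , 2] + rho[, , 3] * p[, , 3]
  log_zedge <- sum(log(pmax(z_edge, 1e-300)))
  # factor normalizers and likelihood averages under the full Gaussian belief
  cav <- update_cavity_stats(msg, problem)
  Tm <- cav$full_t + params$tau
  Vm <- cav$full_delta2
  xi <- problem$x0hat
  gh <- gauss_hermite(gh_points)
  log_zmu <- numeric(M); avg_logw <- numeric(M)
  for (mu in seq_len(M)) {
    if (sigma == 0 && Vm[mu] < 1e-14) {
      a <- xi[mu] * Tm[mu]
      w <- if (a > 0) 1 else if (a < 0) RHO_FLOOR else 0.5
      log_zmu[mu] <- log(w)
      avg_logw[mu] <- log(w)
    } else if (sigma == 0) {
      # hard constraint: W in {0, 1} almost everywhere under the Gaussian
      log_zmu[mu] <- stats::pnorm(xi[mu] * Tm[mu] / sqrt(Vm[mu]),
                                  log.p = TRUE)
      avg_logw[mu] <- 0
    } else {
      log_zmu[mu] <- stats::pnorm(xi[mu] * Tm[mu] / sqrt(sigma^2 + Vm[mu]),
                                  log.p = TRUE)
      lam <- Tm[mu] + sqrt(2 * max(Vm[mu], 0)) * gh$nodes
      lw <- stats::pnorm(xi[mu] * lam / sigma, log.p = TRUE)
      num <- sum(gh$weights / sqrt(pi) * exp(lw) * lw)
      avg_logw[mu] <- num / exp(log_zmu[mu])
    }
  }
  log_zb <- sum(log_zmu) + sum(log_zi) - log_zedge
  log_zb + h * result$expected_n_eff - sum(avg_logw)
}
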