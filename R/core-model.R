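#' Model parameters for the noisy threshold regulation model
#'
#' @param sigma noise standard deviation (>= 0), in expression-log-ratio
#'   units. `sigma = 0` gives the deterministic threshold model.
#' @param h diluting field (>= 0, dimensionless), the sparsity penalty per
#'   nonzero coupling: prior P(J) proportional to exp(-h N_eff(J)).
#' @param tau activation threshold; the target is predicted over-expressed
#'   when the local field exceeds `-tau`, i.e. comparisons use Lambda + tau.
#'   Default 0.
#' @return object of class `model_params`. The inverse temperature is always
#'   taken in the beta -> infinity limit.
#' @export
model_params <- function(sigma = 0, h = 0, tau = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single number >= 0")
  if (!is.numeric(h) || length(h) != 1 || is.na(h) || h < 0)
    stop("'h' must be a single number >= 0")
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau))
    stop("'tau' must be a single finite number")
  structure(list(sigma = sigma, h = h, tau = tau), class = "model_params")
}

#' Ternary coupling vector
#'
#' Validates a vector of couplings J with entries in {-1, 0, +1}: +1 marks an
#' activator, -1 a repressor, 0 no regulatory influence.
#'
#' @param j numeric or integer vector.
#' @return integer vector of class `coupling_vector`.
#' @export
coupling_vector <- function(j) {
  j <- as.integer(j)
  if (any(is.na(j)) || !all(j %in% c(-1L, 0L, 1L)))
    stop("couplings must all be -1, 0 or +1")
  structure(j, class = "coupling_vector")
}

#' Local field of a coupling vector on one pattern
#'
#' Lambda^mu = sum_i J_i x_i^mu, the joint influence of the candidate
#' regulators on the target under pattern mu. Its sign (shifted by the
#' threshold tau) predicts the sign of the target's expression.
#'
#' @param J couplings over the candidate regulators (any vector accepted by
#'   [coupling_vector()]).
#' @param x regulator expression values for one pattern, same length/order
#'   as `J`.
#' @return the local field, a single number.
#' @export
local_field <- function(J, x) {
  J <- coupling_vector(J)
  if (length(J) != length(x))
    stop("length mismatch: ", length(J), " couplings vs ",
         length(x), " inputs")
  sum(as.numeric(J) * as.numeric(x))
}

#' Number of effective (nonzero) couplings
#'
#' @param J a coupling vector.
#' @return integer count of nonzero entries, the quantity penalized by the
#'   diluting field.
#' @export
n_eff <- function(J) sum(coupling_vector(J) != 0L)

#' Deterministic cost: number of violated patterns
#'
#' Counts the patterns whose observed target sign disagrees with the sign of
#' the local field (plus threshold). A zero field (tie) counts as a
#' violation: the deterministic model makes no prediction there, which is
#' scored conservatively.
#'
#' @param J couplings over the problem's regulators.
#' @param problem a [bp_problem()].
#' @param tau activation threshold.
#' @return integer in `[0, M]`.
#' @export
cost_h0 <- function(J, problem, tau = 0) {
  stopifnot(inherits(problem, "bp_problem"))
  J <- coupling_vector(J)
  if (length(J) != nrow(problem$x))
    stop("length mismatch: ", length(J), " couplings vs ",
         nrow(problem$x), " regulators")
  lam <- as.numeric(crossprod(as.numeric(J), problem$x)) + tau
  sum(problem$x0hat * lam <= 0)
}

#' Total cost with sparsity penalty
#'
#' H = H_0(J) + h_scaled * N_eff(J): the deterministic error count plus a
#' penalty per nonzero coupling. With `h_scaled = 0` this reduces to
#' [cost_h0()].
#'
#' @inheritParams cost_h0
#' @param h_scaled sparsity penalty per nonzero coupling, in error-count
#'   units (the diluting field divided by the inverse temperature).
#' @return a single number.
#' @export
total_cost <- function(J, problem, h_scaled = 0, tau = 0) {
  cost_h0(J, problem, tau = tau) + h_scaled * n_eff(J)
}

#' Likelihood of one observed target value
#'
#' Probability of observing the target's sign given the regulator inputs and
#' couplings under Gaussian measurement noise of standard deviation `sigma`:
#' P = Phi(x0hat * (Lambda + tau) / sigma), with Phi the standard normal CDF
#' and x0hat the sign of the observed target value. As sigma -> 0 this
#' sharpens into the deterministic threshold rule (value 1/2 exactly at the
#' step). With `magnitude_weighted = TRUE` the raw target value multiplies
#' the field instead of its sign, so strongly expressed observations weigh
#' more.
#'
#' @param J couplings.
#' @param x regulator inputs for the pattern.
#' @param x0 observed target value (only its sign is used unless
#'   `magnitude_weighted`).
#' @param sigma noise standard deviation, >= 0.
#' @param tau activation threshold.
#' @param magnitude_weighted use the raw target value instead of its sign.
#' @return probability in `[0, 1]`.
#' @export
pattern_likelihood <- function(J, x, x0, sigma, tau = 0,
                               magnitude_weighted = FALSE) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  lam <- local_field(J, x) + tau
  w <- if (magnitude_weighted) x0 else sign(x0)
  arg <- w * lam
  if (sigma == 0) {
    if (arg > 0) 1 else if (arg < 0) 0 else 0.5
  } else {
    stats::pnorm(arg / sigma)
  }
}

#' Unnormalized log-posterior of a coupling vector
#'
#' log P(J | data) up to the J-independent normalizer: the log prior
#' -h N_eff(J) plus the sum of per-pattern log-likelihoods. Patterns with
#' likelihood exactly 0 (possible only at sigma = 0) yield `-Inf`.
#'
#' @param J couplings over the problem's regulators.
#' @param problem a [bp_problem()].
#' @param params a [model_params()].
#' @param magnitude_weighted see [pattern_likelihood()].
#' @return a single number (possibly `-Inf`).
#' @export
log_posterior <- function(J, problem, params, magnitude_weighted = FALSE) {
  stopifnot(inherits(problem, "bp_problem"), inherits(params, "model_params"))
  J <- coupling_vector(J)
  if (length(J) != nrow(problem$x))
    stop("length mismatch: ", length(J), " couplings vs ",
         nrow(problem$x), " regulators")
  lam <- as.numeric(crossprod(as.numeric(J), problem$x)) + params$tau
  w <- if (magnitude_weighted) problem$x0 else problem$x0hat
  arg <- w * lam
  ll <- if (params$sigma == 0) {
    log(ifelse(arg > 0, 1, ifelse(arg < 0, 0, 0.5)))
  } else {
    stats::pnorm(arg / params$sigma, log.p = TRUE)
  }
  -params$h * n_eff(J) + sum(ll)
}

#' Exact posterior marginals by exhaustive enumeration
#'
#' Enumerates all 3^N ternary coupling vectors and computes the normalized
#' posterior marginals P_i(J) for each regulator. Exact but exponential:
#' intended for small problems (N <= 12) and as a cross-check for belief
#' propagation.
#'
#' @inheritParams log_posterior
#' @param max_regulators guard against accidental exponential blow-up.
#' @return list with `marginals` (N x 3 matrix, columns `-1`, `0`, `+1`),
#'   `expected_n_eff`, `entropy` (Shannon entropy of the full posterior, in
#'   nats), and `log_z` (log normalizer relative to the unnormalized scores).
#' @export
enumerate_posterior <- function(problem, params, max_regulators = 12,
                                magnitude_weighted = FALSE) {
  stopifnot(inherits(problem, "bp_problem"), inherits(params, "model_params"))
  N <- nrow(problem$x)
  if (N > max_regulators)
    stop("enumeration over 3^", N, " couplings refused; raise max_regulators")
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), N)))
  lam <- grid %*% problem$x + params$tau           # 3^N x M
  w <- if (magnitude_weighted) problem$x0 else problem$x0hat
  arg <- sweep(lam, 2, w, "*")
  ll <- if (params$sigma == 0) {
    matrix(log(ifelse(arg > 0, 1, ifelse(arg < 0, 0, 0.5))), nrow = nrow(arg))
  } else {
    matrix(stats::pnorm(arg / params$sigma, log.p = TRUE), nrow = nrow(arg))
  }
  neff <- rowSums(grid != 0)
  lp <- rowSums(ll) - params$h * neff
  mx <- max(lp)
  wgt <- exp(lp - mx)
  z <- sum(wgt)
  p <- wgt / z
  marg <- vapply(seq_len(N), function(i) {
    c(sum(p[grid[, i] == -1]), sum(p[grid[, i] == 0]), sum(p[grid[, i] == 1]))
  }, numeric(3))
  marg <- t(marg)
  dimnames(marg) <- list(problem$regulators, c("-1", "0", "+1"))
  nz <- p > 0
  list(marginals = marg,
       expected_n_eff = sum(p * neff),
       entropy = -sum(p[nz] * log(p[nz])),
       log_z = log(z) + mx)
}
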