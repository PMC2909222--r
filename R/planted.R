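#' Planted-network benchmark generator
#'
#' Draws a synthetic steady-state dataset from the model the inference
#' assumes: for each target a random ternary coupling vector with a fixed
#' number of nonzeros is planted over a common pool of candidate regulators;
#' inputs are i.i.d. +/-1 (or standard Gaussian) and the target's expression
#' sign is `sign(Lambda + sigma_gen * eta)` with Gaussian noise eta, so the
#' probability of a sign flip relative to the noiseless threshold rule is
#' `Phi(-|Lambda| / sigma_gen)`.
#'
#' @param n_regulators number of candidate regulators (gene ids `R1`, ...).
#' @param n_targets number of target genes (gene ids `T1`, ...).
#' @param n_eff_true nonzero couplings planted per target.
#' @param M number of patterns (experiments).
#' @param sigma_gen noise standard deviation of the generator (0 = noiseless).
#' @param input `"binary"` (+/-1) or `"gaussian"` regulator inputs.
#' @param seed RNG seed; all randomness in the generator flows from it.
#' @return list with `data` (a steady-state [expression_dataset()] holding
#'   regulator and target rows), `truth` (data.frame `regulator`, `target`,
#'   `sign` of planted links), `couplings` (targets x regulators matrix of
#'   planted J), `candidates`, `targets`.
#' @export
generate_planted_dataset <- function(n_regulators = 20, n_targets = 1,
                                     n_eff_true = 3, M = 100,
                                     sigma_gen = 0.2,
                                     input = c("binary", "gaussian"),
                                     seed = 1) {
  input <- match.arg(input)
  if (n_eff_true > n_regulators)
    stop("n_eff_true cannot exceed n_regulators")
  set.seed(seed)
  regs <- paste0("R", seq_len(n_regulators))
  tgts <- paste0("T", seq_len(n_targets))
  x <- if (input == "binary") {
    matrix(sample(c(-1, 1), n_regulators * M, replace = TRUE),
           n_regulators, M)
  } else {
    matrix(stats::rnorm(n_regulators * M), n_regulators, M)
  }
  J <- matrix(0L, n_targets, n_regulators,
              dimnames = list(tgts, regs))
  y <- matrix(0, n_targets, M)
  for (t in seq_len(n_targets)) {
    nz <- sample.int(n_regulators, n_eff_true)
    J[t, nz] <- sample(c(-1L, 1L), n_eff_true, replace = TRUE)
    lam <- as.numeric(J[t, ] %*% x)
    noise <- if (sigma_gen > 0) stats::rnorm(M, sd = sigma_gen) else 0
    s <- sign(lam + noise)
    s[s == 0] <- 1   # zero field with zero noise: resolve to +1
    y[t, ] <- s
  }
  vals <- rbind(x, y)
  rownames(vals) <- c(regs, tgts)
  colnames(vals) <- paste0("e", seq_len(M))
  idx <- which(J != 0L, arr.ind = TRUE)
  truth <- data.frame(regulator = regs[idx[, 2]], target = tgts[idx[, 1]],
                      sign = J[idx], stringsAsFactors = FALSE)
  truth <- truth[order(truth$target, truth$regulator), ]
  rownames(truth) <- NULL
  list(data = expression_dataset(vals, mode = "steady_state"),
       truth = truth, couplings = J, candidates = regs, targets = tgts)
}
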