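#' Signed Boolean regulatory network
#'
#' A directed network of N genes with signed integer couplings
#' `a[i, j]` in {-1, 0, +1}: the influence of gene j on gene i (+1
#' activating, -1 repressing). Dynamics are synchronous:
#' `s_i(t+1) = 1` if `sum_j a[i,j] s_j(t) > 0`, `0` if `< 0`, and `s_i(t)`
#' (unchanged) at a tie. Self-degradation of a gene is encoded as a -1
#' diagonal entry, which under this tie rule is equivalent to the explicit
#' decay convention "an active gene with zero input switches off".
#'
#' @param a signed integer coupling matrix (rows = targets, cols =
#'   regulators).
#' @param nodes character vector of node names.
#' @return object of class `boolean_network`.
#' @export
boolean_network <- function(a, nodes = rownames(a)) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("coupling matrix must be square")
  if (!all(a %in% c(-1, 0, 1))) stop("couplings must be -1, 0 or +1")
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(a)))
  if (length(nodes) != nrow(a)) stop("one node name per row required")
  storage.mode(a) <- "integer"
  dimnames(a) <- list(nodes, nodes)
  structure(list(a = a, nodes = as.character(nodes)),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network: %d nodes, %d activating / %d repressing links\n",
              length(x$nodes), sum(x$a == 1), sum(x$a == -1)))
  invisible(x)
}

#' The 11-node yeast cell-cycle Boolean network
#'
#' Loads the signed coupling matrix of the 11-node budding-yeast cell-cycle
#' model (nodes Cln3, MBF, SBF, Cln1/2, Cdh1, Swi5, Cdc20&Cdc14, Clb5/6,
#' Sic1, Clb1/2, Mcm1/SFF) shipped as a plain-text fixture. The matrix has
#' 15 activating and 19 repressing entries, five of the latter being -1
#' self-loops encoding self-degradation of Cln3, Cln1/2, Swi5, Cdc20&Cdc14
#' and Mcm1/SFF.
#'
#' @param selfdeg `"selfloop"` keeps the -1 diagonal entries (default);
#'   `"decay"` removes them and records the affected nodes in attribute
#'   `decay_nodes`, applying the equivalent explicit decay rule in
#'   [boolnet_step()]. Both variants generate identical dynamics.
#' @return a [boolean_network()].
#' @export
cellcycle_network <- function(selfdeg = c("selfloop", "decay")) {
  selfdeg <- match.arg(selfdeg)
  path <- system.file("extdata", "cellcycle_network.tsv", package = "grnbp",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  nodes <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  a <- do.call(rbind, lapply(lines[-1], function(l)
    as.integer(strsplit(l, "\t", fixed = TRUE)[[1]])))
  net <- boolean_network(a, nodes)
  if (selfdeg == "decay") {
    dn <- net$nodes[diag(net$a) == -1L]
    diag(net$a)[diag(net$a) == -1L] <- 0L
    attr(net, "decay_nodes") <- dn
  }
  net
}

#' One synchronous update of a Boolean network
#'
#' @param net a [boolean_network()].
#' @param s binary state vector (0/1) of length N.
#' @return the successor state (0/1 vector).
#' @export
boolnet_step <- function(net, s) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(s) != length(net$nodes) || !all(s %in% c(0, 1)))
    stop("state must be a 0/1 vector of length ", length(net$nodes))
  s <- as.integer(s)
  f <- as.vector(net$a %*% s)
  out <- ifelse(f > 0, 1L, ifelse(f < 0, 0L, s))
  decay <- attr(net, "decay_nodes")
  if (!is.null(decay)) {
    idx <- match(decay, net$nodes)
    # explicit decay: an active self-degrading node with zero input turns off
    out[idx] <- ifelse(f[idx] == 0L, 0L, out[idx])
  }
  out
}

state_key <- function(s) sum(as.integer(s) * 2^(seq_along(s) - 1L))

#' Deterministic trajectory to stationarity
#'
#' Iterates [boolnet_step()] from `s0` until a fixed point (or a limit cycle)
#' is reached.
#'
#' @param net a [boolean_network()].
#' @param s0 initial 0/1 state.
#' @param max_steps safety cap.
#' @return list with `states` (matrix, one row per visited state, in order),
#'   `fixed_point` (logical: terminated at a fixed point) and `cycle` (NULL,
#'   or the row indices of a limit cycle).
#' @export
simulate_trajectory <- function(net, s0, max_steps = 2^length(net$nodes)) {
  s <- as.integer(s0)
  states <- list(s)
  keys <- state_key(s)
  cycle <- NULL
  fixed <- FALSE
  for (it in seq_len(max_steps)) {
    nx <- boolnet_step(net, s)
    if (state_key(nx) == state_key(s)) { fixed <- TRUE; break }
    k <- state_key(nx)
    hit <- match(k, keys)
    if (!is.na(hit)) { cycle <- hit:length(keys); break }
    s <- nx
    states[[length(states) + 1L]] <- s
    keys <- c(keys, k)
  }
  out <- do.call(rbind, states)
  colnames(out) <- net$nodes
  list(states = out, fixed_point = fixed, cycle = cycle)
}

#' Exhaustive attractor enumeration
#'
#' Enumerates all 2^N states, finds every fixed point of the synchronous
#' dynamics and the size of its basin of attraction (number of initial
#' states whose trajectory terminates on it). Limit cycles, if any, are
#' reported separately rather than dropped.
#'
#' @param net a [boolean_network()]; N must be small enough for 2^N
#'   enumeration.
#' @return list with `fixed_points` (matrix of states, one per row),
#'   `basin_sizes` (integer vector), and `cycles` (list of state matrices,
#'   empty when all trajectories reach fixed points).
#' @export
enumerate_attractors <- function(net) {
  N <- length(net$nodes)
  if (N > 20) stop("2^", N, " states is too many to enumerate")
  nst <- 2^N
  pow <- 2^(seq_len(N) - 1L)
  states <- t(vapply(0:(nst - 1), function(k)
    as.integer(bitwAnd(bitwShiftR(k, seq_len(N) - 1L), 1L)), integer(N)))
  succ <- apply(states, 1, function(s) state_key(boolnet_step(net, s)))
  fp_keys <- which(succ == 0:(nst - 1)) - 1L
  # terminal state of each trajectory (fixed points reached; cycles marked NA)
  term <- rep(NA_integer_, nst)
  cycles <- list()
  for (k in seq_len(nst)) {
    if (!is.na(term[k])) next
    path <- integer(0)
    cur <- k - 1L
    repeat {
      if (!is.na(term[cur + 1L])) { dest <- term[cur + 1L]; break }
      if (cur %in% fp_keys) { dest <- cur; break }
      if (cur %in% path) {  # limit cycle
        cyc <- path[which(path == cur):length(path)]
        cycles[[length(cycles) + 1L]] <- states[cyc + 1L, , drop = FALSE]
        dest <- -1L - length(cycles)   # sentinel per cycle
        break
      }
      path <- c(path, cur)
      cur <- succ[cur + 1L]
    }
    term[path + 1L] <- dest
    term[k] <- dest
  }
  basins <- vapply(fp_keys, function(f) sum(term == f), integer(1))
  fps <- states[fp_keys + 1L, , drop = FALSE]
  colnames(fps) <- net$nodes
  ord <- order(basins, decreasing = TRUE)
  list(fixed_points = fps[ord, , drop = FALSE],
       basin_sizes = basins[ord],
       cycles = cycles)
}

#' The G1 state: fixed point with the largest basin
#'
#' @param net a [boolean_network()].
#' @return 0/1 state vector.
#' @export
g1_state <- function(net) {
  att <- enumerate_attractors(net)
  if (nrow(att$fixed_points) == 0) stop("network has no fixed point")
  att$fixed_points[1, ]
}

states_to_dataset <- function(net, IN, OUT) {
  # encode 0/1 states as -1/+1 expression values; columns = transitions
  vals <- t(IN) * 2 - 1
  tgt <- t(OUT) * 2 - 1
  rownames(vals) <- rownames(tgt) <- net$nodes
  colnames(vals) <- colnames(tgt) <- paste0("p", seq_len(ncol(vals)))
  expression_dataset(vals, gene_ids = net$nodes, mode = "time_series",
                     target_values = tgt)
}

#' Cell-cycle trajectory dataset
#'
#' Simulates the cell-cycle: starting from G1 (largest-basin fixed point)
#' with the Cln3 cyclin flipped to its active value, the network passes
#' through 13 distinct states before settling back into G1. States are
#' encoded as +/-1 expression values and paired into (t, t+1) transition
#' patterns.
#'
#' @param net the [cellcycle_network()] (or any [boolean_network()] whose
#'   first node plays the Cln3 role).
#' @param include_stationary include the terminal fixed point's
#'   self-transition as a pattern (the observed stationarity of G1); with
#'   `FALSE` a trajectory of K states yields K - 1 patterns.
#' @return a `time_series` [expression_dataset()].
#' @export
cellcycle_dataset <- function(net = cellcycle_network(),
                              include_stationary = TRUE) {
  g1 <- g1_state(net)
  s0 <- g1
  s0[1] <- 1L
  tr <- simulate_trajectory(net, s0)
  S <- tr$states
  IN <- S
  OUT <- rbind(S[-1, , drop = FALSE], S[nrow(S), , drop = FALSE])
  if (!include_stationary) {
    IN <- IN[-nrow(IN), , drop = FALSE]
    OUT <- OUT[-nrow(OUT), , drop = FALSE]
  }
  ds <- states_to_dataset(net, IN, OUT)
  attr(ds, "n_distinct_states") <- nrow(S)
  ds
}

#' Perturbed cell-cycle dataset
#'
#' The cell-cycle trajectory dataset augmented with the trajectories obtained
#' by evolving every configuration at Hamming distance 1 from G1 until
#' stationarity. Duplicate states are collapsed; because the dynamics are
#' deterministic, each distinct state contributes exactly one transition
#' pattern.
#'
#' @inheritParams cellcycle_dataset
#' @return a `time_series` [expression_dataset()] with attribute
#'   `n_distinct_states`.
#' @export
perturbed_cellcycle_dataset <- function(net = cellcycle_network(),
                                        include_stationary = TRUE) {
  g1 <- g1_state(net)
  seen_keys <- character(0)
  states <- list()
  add_state <- function(s) {
    k <- as.character(state_key(s))
    if (!k %in% seen_keys) {
      seen_keys <<- c(seen_keys, k)
      states[[length(states) + 1L]] <<- s
    }
  }
  s0 <- g1
  s0[1] <- 1L
  starts <- c(list(s0), lapply(seq_along(g1), function(i) {
    p <- g1
    p[i] <- 1L - p[i]
    p
  }))
  for (st in starts) {
    tr <- simulate_trajectory(net, st)
    for (r in seq_len(nrow(tr$states))) add_state(tr$states[r, ])
  }
  IN <- do.call(rbind, states)
  OUT <- t(apply(IN, 1, function(s) boolnet_step(net, s)))
  n_distinct <- nrow(IN)
  if (!include_stationary) {
    keep <- apply(IN != OUT, 1, any)
    IN <- IN[keep, , drop = FALSE]
    OUT <- OUT[keep, , drop = FALSE]
  }
  ds <- states_to_dataset(net, IN, OUT)
  attr(ds, "n_distinct_states") <- n_distinct
  ds
}

#' Signed edge list of a Boolean network
#'
#' @param net a [boolean_network()].
#' @param include_self keep self-loops (e.g. self-degradation entries)?
#' @return data.frame with columns `regulator`, `target`, `sign`.
#' @export
network_edges <- function(net, include_self = FALSE) {
  idx <- which(net$a != 0L, arr.ind = TRUE)
  out <- data.frame(regulator = net$nodes[idx[, 2]],
                    target = net$nodes[idx[, 1]],
                    sign = net$a[idx],
                    stringsAsFactors = FALSE)
  if (!include_self) out <- out[out$regulator != out$target, , drop = FALSE]
  rownames(out) <- NULL
  out
}
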