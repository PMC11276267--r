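.LOG_FLOOR <- 1e-300

#' Solver configuration
#'
#' @param beta Positive tradeoff parameter: small values favor compression
#'   (hiding source identity), large values favor prediction of the target.
#' @param objective `"exponential"` (default) or `"linear"`. The linear
#'   Lagrangian trades prediction against `compression / beta`; the
#'   exponential variant penalizes `e^compression / beta` and resolves curves
#'   that are not strictly concave, where the linear relaxation only reaches
#'   the extreme points.
#' @param n_q Bottleneck cardinality `|Q|`. Defaults to the sufficient
#'   cardinality `sum_s |X_s| + 1` (one more than the number of supported
#'   `(s, z)` pairs).
#' @param max_iter Maximum alternating iterations per run.
#' @param tol Convergence threshold on the absolute objective change, in bits.
#' @param n_restarts Number of random restarts; the best objective wins, ties
#'   broken toward lower compression.
#' @param seed Integer seed controlling all random initializations.
#' @return A `solver_config` list.
#' @export
solver_config <- function(beta = 1, objective = c("exponential", "linear"),
                          n_q = NULL, max_iter = 2000L, tol = 1e-10,
                          n_restarts = 5L, seed = 0L) {
  objective <- match.arg(objective)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0,
            tol > 0, max_iter >= 1L, n_restarts >= 0L)
  if (!is.null(n_q)) stopifnot(n_q >= 1L)
  structure(list(beta = beta, objective = objective, n_q = n_q,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "solver_config")
}

# Flattened view of the augmented joint used by the iterative solver: one row
# per supported (s, z) pair, grouped by source.
solver_workspace <- function(joint) {
  stopifnot(inherits(joint, "rb_joint"))
  ns <- length(joint$s_outcomes)
  pairs <- do.call(rbind, lapply(seq_len(ns), function(s) {
    cbind(s = s, z = which(joint$support[s, ]))
  }))
  M <- nrow(pairs)
  ny <- length(joint$y_outcomes)
  J <- matrix(0, M, ny)
  for (j in seq_len(M)) J[j, ] <- joint$p_ysz[, pairs[j, "s"], pairs[j, "z"]]
  pm <- rowSums(J)
  pygsz <- J / ifelse(pm > 0, pm, 1)
  pygsz[pm == 0, ] <- 1 / ny
  by_s <- split(seq_len(M), pairs[, "s"])
  list(joint = joint, pairs = pairs, M = M, ny = ny, ns = ns,
       J = J, pm = pm, pygsz = pygsz,
       py = apply(joint$p_ysz, 1, sum),
       nu = joint$system$nu_s$probs,
       by_s = by_s)
}

#' Bottleneck channel
#'
#' The optimization variable `r(q | s, z)`: one row-stochastic row per
#' supported `(s, z)` pair of the augmented joint (rows outside the support
#' are absent), one column per bottleneck outcome.
#'
#' @param joint An `rb_joint`.
#' @param probs Matrix `[supported (s,z) pair, q]` with rows summing to one.
#'   Pair rows are ordered by source, then by pooled outcome.
#' @return An object of class `rb_bottleneck`.
#' @export
bottleneck_channel <- function(joint, probs) {
  ws <- solver_workspace(joint)
  probs <- as.matrix(probs)
  if (nrow(probs) != ws$M) {
    stop(sprintf("expected %d rows (one per supported (s,z) pair), got %d",
                 ws$M, nrow(probs)), call. = FALSE)
  }
  if (any(probs < -.TOL_STOCH) || any(abs(rowSums(probs) - 1) > .TOL_STOCH)) {
    stop("bottleneck rows must be nonnegative and sum to 1 within 1e-12", call. = FALSE)
  }
  structure(list(q_outcomes = as.character(seq_len(ncol(probs))),
                 probs = pmax(unname(probs), 0),
                 pairs = data.frame(
                   s = joint$s_outcomes[ws$pairs[, "s"]],
                   z = joint$z_outcomes[ws$pairs[, "z"]],
                   stringsAsFactors = FALSE)),
            class = "rb_bottleneck")
}

#' @export
print.rb_bottleneck <- function(x, ...) {
  cat(sprintf("<rb_bottleneck> %d (s,z) rows x |Q|=%d\n",
              nrow(x$probs), ncol(x$probs)))
  invisible(x)
}

#' Random initial bottleneck channel
#'
#' Draws each supported `(s, z)` row from a flat Dirichlet distribution;
#' reproducible from `seed`.
#'
#' @param joint An `rb_joint`.
#' @param config A `solver_config` (supplies `n_q` and, by default, the seed).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An `rb_bottleneck`.
#' @export
init_bottleneck <- function(joint, config = solver_config(), seed = config$seed) {
  ws <- solver_workspace(joint)
  nq <- if (is.null(config$n_q)) ws$M + 1L else as.integer(config$n_q)
  rng <- local_rng(seed)
  g <- matrix(rng$runif_exp(ws$M * nq), ws$M, nq)
  bottleneck_channel(joint, g / rowSums(g))
}

#' Variational joint distribution
#'
#' The inner variable of the alternating scheme: given the current bottleneck
#' channel, the optimal variational distribution is the induced joint itself,
#' `omega(y,s,z,q) = p(y,s,z) r(q|s,z)`.
#'
#' @param joint An `rb_joint`.
#' @param r An `rb_bottleneck`.
#' @return A normalized 4-d array indexed `[y, s, z, q]`.
#' @export
update_variational <- function(joint, r) {
  stopifnot(inherits(joint, "rb_joint"), inherits(r, "rb_bottleneck"))
  ws <- solver_workspace(joint)
  nq <- ncol(r$probs)
  om <- array(0, dim = c(ws$ny, ws$ns, length(joint$z_outcomes), nq),
              dimnames = list(joint$y_outcomes, joint$s_outcomes,
                              joint$z_outcomes, r$q_outcomes))
  for (j in seq_len(ws$M)) {
    om[, ws$pairs[j, "s"], ws$pairs[j, "z"], ] <- outer(ws$J[j, ], r$probs[j, ])
  }
  om
}

# Per-source tables A_s[y, q] = omega(y, s, q) for the flattened workspace and
# a bottleneck matrix r; these drive both the update and all evaluations.
as_tables <- function(ws, rmat) {
  lapply(ws$by_s, function(idx) {
    crossprod(ws$J[idx, , drop = FALSE], rmat[idx, , drop = FALSE])
  })
}

# prediction I(Q;Y|S), compression I(Q;S|Y) (bits) from the per-source tables
pc_from_tables <- function(ws, AsList) {
  B <- Reduce(`+`, AsList)
  pred <- 0
  comp <- 0
  for (s in seq_along(AsList)) {
    As <- AsList[[s]]
    Cs <- colSums(As)
    pos <- As > 0
    if (any(pos)) {
      d1 <- outer(ws$py, Cs)
      pred <- pred + sum(As[pos] * log2(As[pos] / d1[pos]))
      d2 <- ws$nu[s] * B
      comp <- comp + sum(As[pos] * log2(As[pos] / d2[pos]))
    }
  }
  list(pred = max(pred, 0), comp = max(comp, 0))
}

obj_bits <- function(pred, comp, beta, kind) {
  if (kind == "linear") pred - comp / beta
  else pred - exp(comp * log(2)) / (beta * log(2))
}

# One closed-form bottleneck update from arbitrary per-source statistics.
# E[j,q] = sum_y p(y|s,z) [ beta_t ln w(y|q,s) + ln w(q|y) + ln w(z|s,y,q) ],
# with the q-independent ln p(z|s,y) dropped into the normalization.
update_rows <- function(ws, rmat, AsList, B, beta_t) {
  nq <- ncol(rmat)
  E <- matrix(0, ws$M, nq)
  lB <- log(pmax(B, .LOG_FLOOR))
  for (s in seq_along(AsList)) {
    idx <- ws$by_s[[s]]
    P <- ws$pygsz[idx, , drop = FALSE]
    lA <- log(pmax(AsList[[s]], .LOG_FLOOR))
    lC <- log(pmax(colSums(AsList[[s]]), .LOG_FLOOR))
    P1 <- P %*% lA
    PB <- P %*% lB
    E[idx, ] <- (beta_t - 1) * P1 + PB +
      log(pmax(rmat[idx, , drop = FALSE], .LOG_FLOOR)) -
      rep(beta_t * lC, each = length(idx))
  }
  E <- E - apply(E, 1, max)
  R <- exp(E)
  rs <- rowSums(R)
  if (any(rs <= 0) || any(!is.finite(rs))) {
    stop("numerical underflow in bottleneck update: an (s,z) row lost all mass",
         call. = FALSE)
  }
  R / rs
}

#' One bottleneck-channel update step
#'
#' Applies the closed-form maximizer of the alternating objective with
#' respect to the bottleneck channel, for a fixed variational joint `omega`.
#' For the exponential objective the effective inverse temperature
#' `beta * exp(-I_omega(Q;S|Y))` is used (conditional information in nats).
#'
#' @param joint An `rb_joint`.
#' @param omega Variational joint array as returned by [update_variational()].
#' @param config A `solver_config` (supplies `beta` and the objective kind).
#' @return An `rb_bottleneck`.
#' @export
update_bottleneck <- function(joint, omega, config = solver_config()) {
  ws <- solver_workspace(joint)
  nq <- dim(omega)[4]
  # recover the r implied by omega on the support (omega need not equal p*r,
  # but for the closed-form exponent only its conditionals enter)
  rmat <- matrix(0, ws$M, nq)
  AsL <- vector("list", ws$ns)
  for (s in seq_len(ws$ns)) AsL[[s]] <- matrix(0, ws$ny, nq)
  for (j in seq_len(ws$M)) {
    s <- ws$pairs[j, "s"]; z <- ws$pairs[j, "z"]
    om_j <- omega[, s, z, , drop = FALSE]
    dim(om_j) <- c(ws$ny, nq)
    AsL[[s]] <- AsL[[s]] + om_j
    tot <- sum(om_j)
    rmat[j, ] <- if (tot > 0) colSums(om_j) / tot else rep(1 / nq, nq)
  }
  beta_t <- config$beta
  if (config$objective == "exponential") {
    pc <- pc_from_tables(ws, AsL)
    beta_t <- config$beta * exp(-pc$comp * log(2))
  }
  B <- Reduce(`+`, AsL)
  bottleneck_channel(joint, update_rows(ws, rmat, AsL, B, beta_t))
}

# Core alternating loop on the flattened workspace. Returns the final matrix,
# the per-iteration objective trace (bits) and the convergence flag.
rb_iterate <- function(ws, rmat, beta, kind, max_iter, tol) {
  trace <- numeric(max_iter + 1L)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    AsL <- as_tables(ws, rmat)
    pc <- pc_from_tables(ws, AsL)
    obj <- obj_bits(pc$pred, pc$comp, beta, kind)
    trace[it + 1L] <- obj
    if (abs(obj - prev) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    prev <- obj
    beta_t <- if (kind == "exponential") beta * exp(-pc$comp * log(2)) else beta
    B <- Reduce(`+`, AsL)
    rmat <- update_rows(ws, rmat, AsL, B, beta_t)
    it <- it + 1L
  }
  list(rmat = rmat, trace = trace[seq_len(it + 1L)], converged = converged,
       n_iter = it, pred = pc$pred, comp = pc$comp, objective = trace[it + 1L])
}

#' Evaluate a bottleneck channel
#'
#' Computes the prediction `I(Q;Y|S)`, compression `I(Q;S|Y)` and the
#' per-source decomposition (specific conditional mutual informations
#' `I(Q;Y|S=s)` and `I(Q;S=s|Y)`) of the joint induced by `r` over
#' `(Y, S, Z, Q)`.
#'
#' @param joint An `rb_joint`.
#' @param r An `rb_bottleneck`.
#' @return A list with `prediction`, `compression` (bits) and `per_source`, a
#'   data frame with columns `source`, `weight`, `pred_s`, `comp_s` satisfying
#'   `sum(weight * pred_s) == prediction` and likewise for compression.
#' @export
evaluate_point <- function(joint, r) {
  stopifnot(inherits(joint, "rb_joint"), inherits(r, "rb_bottleneck"))
  ws <- solver_workspace(joint)
  eval_decomposed(ws, r$probs)
}

eval_decomposed <- function(ws, rmat) {
  AsL <- as_tables(ws, rmat)
  B <- Reduce(`+`, AsL)
  pred_s <- comp_s <- numeric(ws$ns)
  for (s in seq_len(ws$ns)) {
    As <- AsL[[s]]
    Cs <- colSums(As)
    pos <- As > 0
    d1 <- outer(ws$py, Cs)
    d2 <- ws$nu[s] * B
    pred_s[s] <- sum(As[pos] * log2(As[pos] / d1[pos])) / ws$nu[s]
    comp_s[s] <- sum(As[pos] * log2(As[pos] / d2[pos])) / ws$nu[s]
  }
  pred_s <- pmax(pred_s, 0)
  comp_s <- pmax(comp_s, 0)
  list(prediction = sum(ws$nu * pred_s),
       compression = sum(ws$nu * comp_s),
       per_source = data.frame(source = ws$joint$s_outcomes,
                               weight = ws$nu,
                               pred_s = pred_s, comp_s = comp_s,
                               stringsAsFactors = FALSE))
}

#' Solve the redundancy bottleneck at one tradeoff parameter
#'
#' Alternates the variational and bottleneck-channel updates until the
#' objective changes by less than `config$tol` bits (or `max_iter` is hit),
#' over `config$n_restarts` random initializations plus an optional warm
#' start; the run with the best final objective wins, ties broken toward
#' lower compression.
#'
#' @param joint An `rb_joint`.
#' @param config A `solver_config`.
#' @param warm_start Optional `rb_bottleneck` used as an additional
#'   initialization (the annealing mechanism).
#' @return An object of class `rb_point`: `beta`, `prediction`,
#'   `compression`, `objective` (bits), `per_source` decomposition data frame,
#'   `converged`, `n_iter`, the solved channel `r` and the
#'   `objective_trace`. Non-convergence yields a warning, not an error.
#' @examples
#' jt <- build_joint(make_gate("and"))
#' pt <- solve_rb(jt, solver_config(beta = 10, seed = 1))
#' round(c(pt$prediction, pt$compression), 3)
#' @export
solve_rb <- function(joint, config = solver_config(), warm_start = NULL) {
  stopifnot(inherits(joint, "rb_joint"), inherits(config, "solver_config"))
  ws <- solver_workspace(joint)
  nq <- if (is.null(config$n_q)) ws$M + 1L else as.integer(config$n_q)
  starts <- list()
  if (!is.null(warm_start)) {
    stopifnot(inherits(warm_start, "rb_bottleneck"))
    if (nrow(warm_start$probs) != ws$M) {
      stop("warm start does not match the joint's support", call. = FALSE)
    }
    starts <- list(warm_start$probs)
  }
  if (config$n_restarts > 0) {
    rng <- local_rng(config$seed)
    for (i in seq_len(config$n_restarts)) {
      g <- matrix(rng$runif_exp(ws$M * nq), ws$M, nq)
      starts[[length(starts) + 1L]] <- g / rowSums(g)
    }
  }
  if (length(starts) == 0L) {
    stop("no starting point: need a warm start or n_restarts >= 1", call. = FALSE)
  }
  best <- NULL
  for (r0 in starts) {
    run <- rb_iterate(ws, r0, config$beta, config$objective,
                      config$max_iter, config$tol)
    if (is.null(best) ||
        run$objective > best$objective + 1e-12 ||
        (abs(run$objective - best$objective) <= 1e-12 && run$comp < best$comp)) {
      best <- run
    }
  }
  if (!best$converged) {
    warning(sprintf("solver did not converge within %d iterations at beta=%g",
                    config$max_iter, config$beta))
  }
  ev <- eval_decomposed(ws, best$rmat)
  structure(list(beta = config$beta,
                 prediction = ev$prediction,
                 compression = ev$compression,
                 objective = best$objective,
                 per_source = ev$per_source,
                 converged = best$converged,
                 n_iter = best$n_iter,
                 r = bottleneck_channel(joint, best$rmat),
                 objective_trace = best$trace),
            class = "rb_point")
}

#' @export
print.rb_point <- function(x, ...) {
  cat(sprintf("<rb_point> beta=%g prediction=%.6f compression=%.6f bits (%s, %d iter)\n",
              x$beta, x$prediction, x$compression,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Bottleneck-induced channel from the target to Q
#'
#' Marginalizes the induced joint to the channel `p(q | y)`, the object whose
#' deficiency against each source channel lower-bounds that source's
#' compression contribution.
#'
#' @param joint An `rb_joint`.
#' @param r An `rb_bottleneck`.
#' @return An `rb_channel` from target outcomes to bottleneck outcomes.
#' @export
bottleneck_target_channel <- function(joint, r) {
  ws <- solver_workspace(joint)
  B <- Reduce(`+`, as_tables(ws, r$probs))  # B[y,q] = p(y,q)
  channel(B / ws$py, joint$y_outcomes, r$q_outcomes)
}
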