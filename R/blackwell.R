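# --- polyhedral machinery -----------------------------------------------

# Vertices of the bounded polytope {x : A x <= b} by the double description
# method on the homogenization cone {(x, t) : A x - b t <= 0, t >= 0}.
# Assumes the polytope is bounded and nonempty (then the cone is pointed).
dd_vertices <- function(A, b, tol = 1e-9) {
  A <- as.matrix(A)
  d <- ncol(A)
  Mrows <- cbind(-A, b)                       # m_i . (x, t) >= 0
  Mrows <- rbind(Mrows, c(rep(0, d), 1))      # t >= 0
  # normalize and deduplicate constraint rows
  nr <- sqrt(rowSums(Mrows^2))
  Mrows <- Mrows[nr > tol, , drop = FALSE] / nr[nr > tol]
  Mrows <- unique(round(Mrows, 10))
  m <- nrow(Mrows)
  # initial full-rank subset -> simplicial cone
  qrM <- qr(t(Mrows), tol = 1e-10)
  if (qrM$rank < d + 1) {
    stop("constraint system is rank deficient; polytope is unbounded or degenerate",
         call. = FALSE)
  }
  init <- sort(qrM$pivot[seq_len(d + 1)])
  M0 <- Mrows[init, , drop = FALSE]
  rays <- solve(M0)                           # columns: extreme rays of the init cone
  rays <- rays %*% diag(1 / sqrt(colSums(rays^2)), d + 1)
  slack <- Mrows %*% rays                     # [constraint, ray]
  processed <- init
  for (i in setdiff(seq_len(m), init)) {
    s <- slack[i, ]
    pos <- which(s > tol); neg <- which(s < -tol); zer <- which(abs(s) <= tol)
    if (length(neg) == 0L) { processed <- c(processed, i); next }
    tight <- abs(slack[processed, , drop = FALSE]) <= tol  # [processed, ray]
    newcols <- NULL
    for (p in pos) for (n in neg) {
      zpn <- tight[, p] & tight[, n]
      # combinatorial adjacency: no third ray is tight on a superset of zpn
      others <- setdiff(seq_len(ncol(rays)), c(p, n))
      adjacent <- TRUE
      if (length(others) > 0) {
        covered <- colSums(tight[zpn, others, drop = FALSE]) == sum(zpn)
        adjacent <- !any(covered)
      }
      if (adjacent) {
        v <- s[p] * rays[, n] - s[n] * rays[, p]
        nv <- sqrt(sum(v^2))
        if (nv > tol) newcols <- cbind(newcols, v / nv)
      }
    }
    keep <- c(pos, zer)
    rays <- cbind(rays[, keep, drop = FALSE], newcols)
    # dedupe rays
    key <- apply(round(rays, 9), 2, paste, collapse = ",")
    rays <- rays[, !duplicated(key), drop = FALSE]
    processed <- c(processed, i)
    slack <- Mrows %*% rays
  }
  tcoord <- rays[d + 1, ]
  if (any(tcoord < -tol)) stop("internal error: negative homogenizing coordinate")
  verts <- rays[seq_len(d), tcoord > tol, drop = FALSE]
  verts <- sweep(verts, 2, tcoord[tcoord > tol], "/")
  t(verts)
}

# Halfspace description of the garbling polytope: stacked entries of one
# garbling channel kappa_s (|X_s| x n_q, row-major by source) per source,
# subject to row-stochasticity, nonnegativity, and the agreement constraints
# kappa_1 o p_{X1|Y} = kappa_s o p_{Xs|Y}. Returns the equality system and a
# strictly feasible point (the constant uniform garbling).
blackwell_polytope <- function(system, n_q) {
  chans <- lapply(system$sources, function(ch) ch$probs)  # [y, x]
  nx <- vapply(chans, ncol, integer(1))
  ns <- length(chans)
  ny <- nrow(chans[[1]])
  off <- c(0, cumsum(nx * n_q))
  nvar <- off[ns + 1]
  vindex <- function(s, x, q) off[s] + (x - 1) * n_q + q
  eqs <- list(); rhs <- numeric(0)
  for (s in seq_len(ns)) for (x in seq_len(nx[s])) {
    row <- numeric(nvar)
    row[vindex(s, x, seq_len(n_q))] <- 1
    eqs[[length(eqs) + 1L]] <- row
    rhs <- c(rhs, 1)
  }
  for (s in seq(2, length.out = ns - 1)) for (q in seq_len(n_q)) for (y in seq_len(ny)) {
    row <- numeric(nvar)
    row[vindex(1, seq_len(nx[1]), q)] <- chans[[1]][y, ]
    row[vindex(s, seq_len(nx[s]), q)] <- row[vindex(s, seq_len(nx[s]), q)] - chans[[s]][y, ]
    eqs[[length(eqs) + 1L]] <- row
    rhs <- c(rhs, 0)
  }
  list(E = do.call(rbind, eqs), f = rhs, v0 = rep(1 / n_q, nvar),
       off = off, nx = nx, n_q = n_q)
}

#' Exact Blackwell redundancy by vertex enumeration
#'
#' Maximizes `I(Q;Y)` over all variables `Q` that are a garbling of every
#' source channel. The feasible set of garbling channels is a polytope; a
#' convex objective attains its maximum at a vertex, so the problem is solved
#' exactly by enumerating all vertices (double description after eliminating
#' the equality constraints through a null-space parametrization) and scoring
#' the induced channel `p(q|y) = kappa_1 o p_{X1|Y}` at each. The result does
#' not depend on the source weights.
#'
#' @param system An `rb_system`, small enough for enumeration: the reduced
#'   polytope dimension is capped at 60.
#' @param n_q Bottleneck cardinality; defaults to the sufficient
#'   `sum_s |X_s| - n + 1`.
#' @return A list with `redundancy` (bits), the arg-max `channel` (an
#'   `rb_channel` from target outcomes to `Q`), and `n_vertices` scored.
#' @examples
#' blackwell_redundancy(make_gate("and"))$redundancy
#' @export
blackwell_redundancy <- function(system, n_q = NULL) {
  stopifnot(inherits(system, "rb_system"))
  nx <- vapply(system$sources, function(ch) length(ch$output_outcomes), integer(1))
  if (is.null(n_q)) n_q <- max(sum(nx) - length(nx) + 1L, 1L)
  pol <- blackwell_polytope(system, n_q)
  # eliminate equalities: v = v0 + N x with N an orthonormal null-space basis
  sv <- svd(pol$E, nu = 0, nv = ncol(pol$E))
  rank <- sum(sv$d > max(dim(pol$E)) * max(sv$d) * 1e-12)
  if (rank == ncol(pol$E)) {
    Nmat <- NULL
  } else {
    Nmat <- sv$v[, seq(rank + 1, ncol(pol$E)), drop = FALSE]
  }
  if (is.null(Nmat)) {
    vmat <- matrix(pol$v0, nrow = 1)
  } else {
    dim_red <- ncol(Nmat)
    if (dim_red > 60) {
      stop(sprintf(paste0("reduced garbling polytope has dimension %d > 60; ",
                          "vertex enumeration refused. Use the iterative RB ",
                          "solver at small beta instead."), dim_red),
           call. = FALSE)
    }
    verts <- dd_vertices(-Nmat, pol$v0)
    vmat <- verts %*% t(Nmat)
    vmat <- sweep(vmat, 2, pol$v0, "+")
  }
  py <- system$p_y$probs
  p1 <- system$sources[[1]]$probs
  best <- -Inf; best_q <- NULL; seen <- character(0)
  for (i in seq_len(nrow(vmat))) {
    k1 <- matrix(vmat[i, seq(pol$off[1] + 1, pol$off[2])],
                 nrow = pol$nx[1], ncol = n_q, byrow = TRUE)
    k1 <- pmin(pmax(k1, 0), 1)
    qy <- p1 %*% k1                        # p(q | y), [y, q]
    key <- paste(round(qy, 9), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    val <- mutual_information(py * qy)
    if (val > best) { best <- val; best_q <- qy }
  }
  ch <- channel(best_q / rowSums(best_q), system$p_y$outcomes,
                as.character(seq_len(n_q)))
  list(redundancy = best, channel = ch, n_vertices = length(seen))
}

# --- Blackwell order and deficiency -------------------------------------

# Euclidean projection of each row onto the probability simplex (Duchi et al.)
project_rows_simplex <- function(m) {
  t(apply(m, 1, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u - (css - 1) / seq_along(u) > 0))
    pmax(v - (css[rho] - 1) / rho, 0)
  }))
}

#' Test the Blackwell (degradation) order between two channels
#'
#' Decides whether `b` is a garbling of `c`, i.e. whether a row-stochastic
#' `kappa` exists with `kappa o c = b`. The convex feasibility problem is
#' solved by accelerated projected-gradient minimization of the squared
#' residual over the product of simplices; feasibility is declared when the
#' maximum absolute residual falls below `tol`.
#'
#' @param b,c `rb_channel`s sharing the same input (target) alphabet.
#' @param tol Residual tolerance for declaring feasibility.
#' @return `TRUE` iff `b` is less Blackwell-informative than `c`.
#' @examples
#' bsc <- function(e) channel(rbind(c(1 - e, e), c(e, 1 - e)))
#' is_blackwell_leq(bsc(0.2), bsc(0.1))  # TRUE: extra noise is a garbling
#' @export
is_blackwell_leq <- function(b, c, tol = 1e-7) {
  stopifnot(inherits(b, "rb_channel"), inherits(c, "rb_channel"))
  if (!identical(b$input_outcomes, c$input_outcomes)) {
    stop("channels must share the input alphabet", call. = FALSE)
  }
  Cm <- c$probs; Bm <- b$probs
  nc <- ncol(Cm); nb <- ncol(Bm)
  K <- matrix(1 / nb, nc, nb)
  L <- 2 * sum(Cm^2) + 1e-12
  Kprev <- K; tk <- 1
  for (it in seq_len(20000L)) {
    Yk <- K + ((tk - 1) / (tk + 2)) * (K - Kprev)
    Rz <- Cm %*% Yk - Bm
    G <- 2 * crossprod(Cm, Rz)
    Kprev <- K
    K <- project_rows_simplex(Yk - G / L)
    tk <- tk + 1
    res <- max(abs(Cm %*% K - Bm))
    if (res <= tol * 0.1) break
    if (it %% 500 == 0) {
      # restart momentum occasionally for robustness
      tk <- 1; Kprev <- K
    }
  }
  max(abs(Cm %*% K - Bm)) <= tol
}

#' KL-weighted channel deficiency
#'
#' `delta_D(c, b) = min over row-stochastic kappa of
#' sum_y p(y) D( (kappa o c)(.|y) || b(.|y) )` in bits: how far `b` is from
#' being a garbling of `c`, weighted by the target marginal. Zero iff
#' `b` is Blackwell-below `c` (up to tolerance). Minimized with multiplicative
#' (exponentiated-gradient) updates with backtracking; the problem is convex
#' and smooth on the interior of the simplex product.
#'
#' @param c,b `rb_channel`s sharing the input alphabet with `p_y`'s support.
#' @param p_y `rb_dist` over the shared input alphabet.
#' @param tol Convergence threshold on the objective change, bits.
#' @param max_iter Iteration cap.
#' @return Deficiency in bits; `Inf` if absolute continuity fails for every
#'   admissible `kappa`.
#' @export
deficiency <- function(c, b, p_y, tol = 1e-10, max_iter = 5000L) {
  stopifnot(inherits(b, "rb_channel"), inherits(c, "rb_channel"),
            inherits(p_y, "rb_dist"))
  if (!identical(b$input_outcomes, c$input_outcomes) ||
      !identical(p_y$outcomes, c$input_outcomes)) {
    stop("channels and target marginal must share the input alphabet", call. = FALSE)
  }
  py <- p_y$probs
  Cm <- c$probs; Bm <- b$probs
  nc <- ncol(Cm); nb <- ncol(Bm)
  # kappa(x -> j) must be zero wherever it would push mass onto a zero of b
  allowed <- matrix(TRUE, nc, nb)
  for (x in seq_len(nc)) for (j in seq_len(nb)) {
    if (any(Cm[, x] > 0 & Bm[, j] == 0 & py > 0)) allowed[x, j] <- FALSE
  }
  live <- colSums(Cm * py) > 0     # kappa rows that actually receive mass
  if (any(live & rowSums(allowed) == 0)) return(Inf)
  K <- allowed * 1
  K[rowSums(K) == 0, ] <- 1        # dead rows: uniform, irrelevant
  K <- K / rowSums(K)
  objective <- function(K) {
    Mm <- Cm %*% K
    tot <- 0
    for (y in seq_len(nrow(Cm))) {
      if (py[y] > 0) tot <- tot + py[y] * xlog2x_over(Mm[y, ], Bm[y, ])
    }
    tot
  }
  grad <- function(K) {
    Mm <- Cm %*% K
    ratio <- matrix(0, nrow(Mm), ncol(Mm))
    pos <- Mm > 0
    ratio[pos] <- log(Mm[pos] / pmax(Bm[pos], .LOG_FLOOR)) + 1
    crossprod(Cm, (py * ratio)) / log(2)
  }
  f <- objective(K)
  if (!is.finite(f)) return(Inf)
  eta <- 1
  for (it in seq_len(max_iter)) {
    g <- grad(K)
    improved <- FALSE
    for (bt in seq_len(40L)) {
      Knew <- K * exp(-eta * (g - apply(g, 1, min)))
      Knew[!allowed] <- 0
      rs <- rowSums(Knew)
      Knew <- Knew / ifelse(rs > 0, rs, 1)
      fnew <- objective(Knew)
      if (is.finite(fnew) && fnew <= f) { improved <- TRUE; break }
      eta <- eta / 2
    }
    if (!improved) break
    delta <- f - fnew
    K <- Knew; f <- fnew
    if (eta < 1) eta <- eta * 1.5
    if (delta < tol) break
  }
  max(f, 0)
}
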