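# Shared fixtures and independent oracles.

# Session-level memo for the expensive annealed curves so several test files
# can share one solve.
.fixture_cache <- new.env(parent = emptyenv())

fixture_system <- function(name) {
  switch(name,
    copy0 = suppressMessages(make_gate("copy", eps = 0)),
    make_gate(name))
}

fixture_joint <- function(name) {
  key <- paste0("joint_", name)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_joint(fixture_system(name))
  }
  .fixture_cache[[key]]
}

# Default-config annealed curve (50 log-spaced beta, 5 restarts, seed 42).
fixture_curve <- function(name) {
  key <- paste0("curve_", name)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressWarnings(
      anneal_curve(fixture_joint(name), default_beta_grid(),
                   solver_config(seed = 42)))
  }
  .fixture_cache[[key]]
}

fixture_blackwell <- function(name) {
  key <- paste0("bw_", name)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- blackwell_redundancy(fixture_system(name))$redundancy
  }
  .fixture_cache[[key]]
}

# --- independent oracles -------------------------------------------------

# Mutual information by direct term-by-term summation of the definition.
mi_oracle <- function(tab) {
  pa <- rowSums(tab); pb <- colSums(tab)
  tot <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) tot <- tot + tab[i, j] * log2(tab[i, j] / (pa[i] * pb[j]))
  }
  tot
}

# Conditional MI I(A;B|C) by direct summation, conditioning on axis 3.
cmi_oracle <- function(tab) {
  stopifnot(length(dim(tab)) == 3)
  tot <- 0
  for (k in seq_len(dim(tab)[3])) {
    pc <- sum(tab[, , k])
    if (pc > 0) tot <- tot + pc * mi_oracle(tab[, , k] / pc)
  }
  tot
}

# Prediction/compression of a bottleneck channel by brute-force summation
# over the full induced joint p(y,s,z,q) -- independent of the package's
# vectorized evaluation path.
eval_oracle <- function(joint, r) {
  om <- update_variational(joint, r)      # p(y,s,z,q)
  pysq <- apply(om, c(1, 2, 4), sum)      # p(y, s, q)
  d <- dim(pysq)
  pred <- comp <- 0
  for (s in seq_len(d[2])) {              # I(Q;Y|S): condition on s
    slice <- pysq[, s, , drop = FALSE]; dim(slice) <- d[c(1, 3)]
    ps <- sum(slice)
    if (ps > 0) pred <- pred + ps * mi_oracle(slice / ps)
  }
  for (y in seq_len(d[1])) {              # I(Q;S|Y): condition on y
    slice <- pysq[y, , , drop = FALSE]; dim(slice) <- d[c(2, 3)]
    py <- sum(slice)
    if (py > 0) comp <- comp + py * mi_oracle(slice / py)
  }
  list(prediction = pred, compression = comp)
}

# Deficiency oracle: exhaustive grid over 2x2 row-stochastic garblings.
deficiency_grid_oracle <- function(c_ch, b_ch, py, step = 1e-3) {
  a <- rep(seq(0, 1, step), each = length(seq(0, 1, step)))
  b2 <- rep(seq(0, 1, step), times = length(seq(0, 1, step)))
  Cm <- c_ch$probs; Bm <- b_ch$probs
  xl <- function(p, q) ifelse(p > 0, p * log2(p / pmax(q, 1e-300)), 0)
  tot <- 0
  for (y in seq_len(nrow(Cm))) {
    m1 <- Cm[y, 1] * a + Cm[y, 2] * b2       # mass on output 1
    tot <- tot + py[y] * (xl(m1, Bm[y, 1]) + xl(1 - m1, Bm[y, 2]))
  }
  min(tot)
}
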