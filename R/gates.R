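#' Benchmark gate systems
#'
#' Constructs the standard discrete benchmark systems used throughout the
#' partial-information-decomposition literature:
#' \describe{
#'   \item{`unique`}{Uniform binary target; `X1` a noiseless copy of the
#'     target, `X2` an independent uniform bit.}
#'   \item{`and`}{Target `Y = X1 AND X2` of two independent uniform bits,
#'     expressed channel-wise: `p(Y=0) = 3/4` and both source channels equal
#'     `[(2/3, 1/3), (0, 1)]`.}
#'   \item{`bsc`}{Uniform binary target observed through binary symmetric
#'     channels with per-source error probabilities `eps` (default
#'     `c(0.1, 0.1, 0.2, 0.5)`).}
#'   \item{`spin_overlap`}{Target of three uniform binary spins
#'     `Y = (Y1,Y2,Y3)`; `X1 = X2 = (Y1,Y2)` and `X3 = (Y1,Y3)`.}
#'   \item{`copy`}{Two binary sources with `P(X1 = X2) = 1 - eps/2`
#'     (`p(x1,x2) = 1/2 - eps/4` when equal, `eps/4` otherwise); the target is
#'     the pair `Y = (X1, X2)`. `eps = 0` gives perfect correlation, `eps = 1`
#'     independence. Target outcomes with zero probability (at `eps = 0`) are
#'     pruned, since the target marginal must have full support.}
#' }
#'
#' @param name One of `"unique"`, `"and"`, `"bsc"`, `"spin_overlap"`,
#'   `"copy"`.
#' @param eps Error probabilities: a vector (one per source) for `"bsc"`, a
#'   single correlation parameter in `[0, 1]` for `"copy"`. Ignored otherwise.
#' @param nu_s Optional source weights; uniform by default.
#' @return An `rb_system`.
#' @examples
#' make_gate("and")$sources$X1$probs
#' @export
make_gate <- function(name = c("unique", "and", "bsc", "spin_overlap", "copy"),
                      eps = NULL, nu_s = NULL) {
  name <- match.arg(name)
  switch(name,
    unique = {
      y <- discrete_dist(c(0.5, 0.5), c("0", "1"))
      x1 <- channel(diag(2), c("0", "1"), c("0", "1"))
      x2 <- channel(matrix(0.5, 2, 2), c("0", "1"), c("0", "1"))
      source_system(y, list(X1 = x1, X2 = x2), nu_s)
    },
    and = {
      y <- discrete_dist(c(3 / 4, 1 / 4), c("0", "1"))
      ch <- channel(rbind(c(2 / 3, 1 / 3), c(0, 1)), c("0", "1"), c("0", "1"))
      source_system(y, list(X1 = ch, X2 = ch), nu_s)
    },
    bsc = {
      if (is.null(eps)) eps <- c(0.1, 0.1, 0.2, 0.5)
      if (any(eps < 0 | eps > 1)) stop("BSC error probabilities must lie in [0,1]", call. = FALSE)
      y <- discrete_dist(c(0.5, 0.5), c("0", "1"))
      srcs <- lapply(eps, function(e) {
        channel(rbind(c(1 - e, e), c(e, 1 - e)), c("0", "1"), c("0", "1"))
      })
      names(srcs) <- paste0("X", seq_along(eps))
      source_system(y, srcs, nu_s)
    },
    spin_overlap = {
      g <- expand.grid(b3 = 0:1, b2 = 0:1, b1 = 0:1)
      bits3 <- sort(paste0(g$b1, g$b2, g$b3))
      y <- discrete_dist(rep(1 / 8, 8), bits3)
      pair_out <- c("00", "01", "10", "11")
      det_channel <- function(f) {
        m <- matrix(0, 8, 4, dimnames = list(bits3, pair_out))
        for (i in seq_along(bits3)) m[i, f(bits3[i])] <- 1
        channel(m, bits3, pair_out)
      }
      x12 <- det_channel(function(yy) substr(yy, 1, 2))
      x3 <- det_channel(function(yy) paste0(substr(yy, 1, 1), substr(yy, 3, 3)))
      source_system(y, list(X1 = x12, X2 = x12, X3 = x3), nu_s)
    },
    copy = {
      if (is.null(eps)) eps <- 0
      if (length(eps) != 1 || eps < 0 || eps > 1) {
        stop("the copy gate takes a single correlation parameter eps in [0,1]", call. = FALSE)
      }
      pairs <- c("00", "01", "10", "11")
      py <- ifelse(substr(pairs, 1, 1) == substr(pairs, 2, 2),
                   1 / 2 - eps / 4, eps / 4)
      keep <- py > 0
      if (!all(keep)) {
        message(sprintf("copy gate: pruned %d zero-probability target outcome(s): %s",
                        sum(!keep), paste(pairs[!keep], collapse = ", ")))
      }
      pairs <- pairs[keep]; py <- py[keep]
      y <- discrete_dist(py, pairs)
      det_channel <- function(pos) {
        m <- matrix(0, length(pairs), 2, dimnames = list(pairs, c("0", "1")))
        for (i in seq_along(pairs)) m[i, substr(pairs[i], pos, pos)] <- 1
        channel(m, pairs, c("0", "1"))
      }
      source_system(y, list(X1 = det_channel(1), X2 = det_channel(2)), nu_s)
    })
}

#' Random source system
#'
#' Draws a full-support target marginal and row-stochastic source channels
#' from flat Dirichlet distributions, with uniform source weights. Intended
#' for property-style testing; reproducible from `seed`.
#'
#' @param n_sources Number of sources.
#' @param y_card Target alphabet size.
#' @param x_cards Output alphabet size per source (recycled to `n_sources`).
#'   Source alphabets share labels, so pooled outcomes merge across sources.
#' @param seed Integer seed.
#' @return An `rb_system`.
#' @export
random_system <- function(n_sources = 2L, y_card = 3L, x_cards = 3L, seed = 1L) {
  x_cards <- rep_len(x_cards, n_sources)
  rng <- local_rng(seed)
  rdirich <- function(k) {
    g <- rng$runif_exp(k)
    g / sum(g)
  }
  py <- rdirich(y_card)
  # keep full support: mix with uniform to bound entries away from zero
  py <- 0.99 * py + 0.01 / y_card
  y <- discrete_dist(py, paste0("y", seq_len(y_card)))
  srcs <- lapply(seq_len(n_sources), function(s) {
    m <- t(vapply(seq_len(y_card), function(i) rdirich(x_cards[s]), numeric(x_cards[s])))
    if (x_cards[s] == 1L) m <- matrix(1, y_card, 1)
    channel(m, y$outcomes, paste0("o", seq_len(x_cards[s])))
  })
  names(srcs) <- paste0("X", seq_len(n_sources))
  source_system(y, srcs)
}

# Seed-scoped RNG helper: evaluates draws under `seed` without disturbing the
# caller's RNG state.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  state <- new.env()
  state$saved <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  state$cur <- get(".Random.seed", envir = globalenv())
  restore <- function() {
    if (is.null(state$saved)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", state$saved, envir = globalenv())
    }
  }
  draw <- function(fn) {
    assign(".Random.seed", state$cur, envir = globalenv())
    out <- fn()
    state$cur <- get(".Random.seed", envir = globalenv())
    restore()
    out
  }
  list(
    runif_exp = function(n) draw(function() stats::rexp(n)),
    runif = function(n) draw(function() stats::runif(n))
  )
}
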