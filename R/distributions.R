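.TOL_STOCH <- 1e-12

#' Discrete probability distribution
#'
#' A finite distribution over an ordered set of opaque outcome labels.
#' Probabilities must be nonnegative and sum to one within `1e-12`.
#'
#' @param probs Numeric vector of probabilities.
#' @param outcomes Character vector of outcome labels; defaults to the names
#'   of `probs` or `"1","2",...`. Arbitrary label types are coerced to
#'   character.
#' @return An object of class `rb_dist` with fields `outcomes` and `probs`.
#' @examples
#' discrete_dist(c(0.5, 0.5), c("0", "1"))
#' @export
discrete_dist <- function(probs, outcomes = NULL) {
  probs <- as.numeric(probs)
  if (is.null(outcomes)) {
    outcomes <- if (!is.null(names(probs))) names(probs) else as.character(seq_along(probs))
  }
  outcomes <- as.character(outcomes)
  if (length(outcomes) != length(probs)) {
    stop("`outcomes` and `probs` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(outcomes)) stop("duplicate outcome labels", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < -.TOL_STOCH)) {
    stop("probabilities must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > .TOL_STOCH) {
    stop(sprintf("probabilities sum to %.15g, not 1", sum(probs)), call. = FALSE)
  }
  probs <- pmax(probs, 0)
  structure(list(outcomes = outcomes, probs = unname(probs)), class = "rb_dist")
}

#' @export
print.rb_dist <- function(x, ...) {
  cat("<rb_dist> over {", paste(x$outcomes, collapse = ", "), "}\n")
  print(stats::setNames(x$probs, x$outcomes))
  invisible(x)
}

#' Discrete memoryless channel
#'
#' A conditional distribution `p(output | input)` stored as a row-stochastic
#' matrix: one row per input outcome, one column per output outcome. Every row
#' must sum to one within `1e-12`.
#'
#' @param probs Numeric matrix `[input, output]` of conditional probabilities.
#' @param input_outcomes,output_outcomes Character labels for the conditioning
#'   and output alphabets; default to the dimnames of `probs`.
#' @return An object of class `rb_channel`.
#' @examples
#' bsc <- channel(rbind(c(0.9, 0.1), c(0.1, 0.9)), c("0", "1"), c("0", "1"))
#' @export
channel <- function(probs, input_outcomes = NULL, output_outcomes = NULL) {
  probs <- as.matrix(probs)
  if (is.null(input_outcomes)) {
    input_outcomes <- if (!is.null(rownames(probs))) rownames(probs) else as.character(seq_len(nrow(probs)))
  }
  if (is.null(output_outcomes)) {
    output_outcomes <- if (!is.null(colnames(probs))) colnames(probs) else as.character(seq_len(ncol(probs)))
  }
  input_outcomes <- as.character(input_outcomes)
  output_outcomes <- as.character(output_outcomes)
  if (nrow(probs) != length(input_outcomes) || ncol(probs) != length(output_outcomes)) {
    stop("channel matrix does not match alphabet sizes", call. = FALSE)
  }
  if (anyDuplicated(input_outcomes) || anyDuplicated(output_outcomes)) {
    stop("duplicate outcome labels", call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < -.TOL_STOCH)) {
    stop("channel entries must be finite and nonnegative", call. = FALSE)
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > .TOL_STOCH)) {
    stop("every channel row must sum to 1 within 1e-12", call. = FALSE)
  }
  probs <- pmax(probs, 0)
  dimnames(probs) <- list(input_outcomes, output_outcomes)
  structure(list(input_outcomes = input_outcomes,
                 output_outcomes = output_outcomes,
                 probs = probs),
            class = "rb_channel")
}

#' @export
print.rb_channel <- function(x, ...) {
  cat(sprintf("<rb_channel> %d -> %d outcomes\n",
              length(x$input_outcomes), length(x$output_outcomes)))
  print(x$probs)
  invisible(x)
}

#' Compose two channels
#'
#' Returns the channel obtained by feeding the output of `base` through the
#' post-processing (garbling) channel `kappa`, i.e. the matrix product
#' `p(out|in) = sum_m kappa(out|m) base(m|in)`.
#'
#' @param kappa Post-processing `rb_channel`; its input alphabet must equal
#'   `base`'s output alphabet.
#' @param base Upstream `rb_channel`.
#' @return An `rb_channel` from `base`'s input alphabet to `kappa`'s output
#'   alphabet.
#' @export
compose_channels <- function(kappa, base) {
  stopifnot(inherits(kappa, "rb_channel"), inherits(base, "rb_channel"))
  if (!identical(kappa$input_outcomes, base$output_outcomes)) {
    stop("alphabet mismatch: kappa's inputs must equal base's outputs", call. = FALSE)
  }
  m <- base$probs %*% kappa$probs
  # clip roundoff so the constructor's stochasticity check passes
  m <- m / rowSums(m)
  channel(m, base$input_outcomes, kappa$output_outcomes)
}

#' Source system: the problem definition
#'
#' Bundles the target marginal `p(y)` (full support required), an ordered set
#' of named source channels `p(x_s | y)` all sharing the target alphabet, and
#' full-support source weights `nu_s` (uniform by default).
#'
#' @param p_y `rb_dist` over target outcomes; strictly positive.
#' @param sources Named list of `rb_channel`s with input alphabet equal to
#'   `p_y$outcomes`. Unnamed lists get names `"X1","X2",...`.
#' @param nu_s Optional `rb_dist` (or bare numeric vector) of source weights;
#'   strictly positive. Defaults to uniform.
#' @return An object of class `rb_system`.
#' @examples
#' sys <- make_gate("unique")
#' prediction_bound(sys)
#' @export
source_system <- function(p_y, sources, nu_s = NULL) {
  stopifnot(inherits(p_y, "rb_dist"))
  if (length(sources) < 1L) stop("need at least one source", call. = FALSE)
  if (any(p_y$probs <= 0)) {
    stop("target marginal must have full support (prune zero-probability outcomes first)",
         call. = FALSE)
  }
  nm <- names(sources)
  if (is.null(nm) || any(nm == "")) nm <- paste0("X", seq_along(sources))
  names(sources) <- nm
  for (s in seq_along(sources)) {
    ch <- sources[[s]]
    if (!inherits(ch, "rb_channel")) stop("each source must be an rb_channel", call. = FALSE)
    if (!identical(ch$input_outcomes, p_y$outcomes)) {
      stop(sprintf("source '%s' does not share the target alphabet", nm[s]), call. = FALSE)
    }
  }
  if (is.null(nu_s)) {
    nu_s <- discrete_dist(rep(1 / length(sources), length(sources)), nm)
  } else if (!inherits(nu_s, "rb_dist")) {
    nu_s <- discrete_dist(as.numeric(nu_s), nm)
  }
  if (length(nu_s$probs) != length(sources)) {
    stop("`nu_s` must have one weight per source", call. = FALSE)
  }
  if (any(nu_s$probs <= 0)) {
    stop("source weights must have full support", call. = FALSE)
  }
  structure(list(p_y = p_y, sources = sources, nu_s = nu_s), class = "rb_system")
}

#' @export
print.rb_system <- function(x, ...) {
  cat(sprintf("<rb_system> %d target outcomes, %d sources (%s)\n",
              length(x$p_y$outcomes), length(x$sources),
              paste(names(x$sources), collapse = ", ")))
  invisible(x)
}

xlog2x_over <- function(p, q) {
  # sum p * log2(p/q) with 0 log 0 := 0; +Inf when p > 0 where q == 0
  pos <- p > 0
  if (!any(pos)) return(0)
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Shannon entropy in bits
#'
#' @param d An `rb_dist` or a bare numeric probability vector.
#' @return Entropy in bits, with the convention `0 log 0 = 0`.
#' @export
entropy <- function(d) {
  p <- if (inherits(d, "rb_dist")) d$probs else as.numeric(d)
  pos <- p > 0
  -sum(p[pos] * log2(p[pos]))
}

#' Kullback-Leibler divergence in bits
#'
#' `D(p || q)` in bits over a shared outcome ordering; returns `Inf` when `p`
#' puts mass where `q` has none.
#'
#' @param p,q `rb_dist` objects (or numeric vectors) over the same ordered
#'   alphabet.
#' @return Nonnegative divergence in bits (zero iff `p == q`).
#' @export
kl_divergence <- function(p, q) {
  if (inherits(p, "rb_dist") && inherits(q, "rb_dist")) {
    if (!identical(p$outcomes, q$outcomes)) {
      stop("`p` and `q` must share the same outcome ordering", call. = FALSE)
    }
    p <- p$probs; q <- q$probs
  }
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  xlog2x_over(as.numeric(p), as.numeric(q))
}

check_normalized <- function(tab, tol = 1e-9) {
  if (any(tab < -tol)) stop("joint table has negative entries", call. = FALSE)
  if (abs(sum(tab) - 1) > tol) {
    stop(sprintf("joint table sums to %.12g, not 1", sum(tab)), call. = FALSE)
  }
}

#' Mutual information of a two-way joint table
#'
#' @param tab Numeric matrix `p(a, b)` summing to one.
#' @return `I(A;B)` in bits.
#' @export
mutual_information <- function(tab) {
  tab <- as.matrix(tab)
  check_normalized(tab)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  pos <- tab > 0
  sum(tab[pos] * log2(tab[pos] / outer(pa, pb)[pos]))
}

#' Conditional mutual information of a three-way joint table
#'
#' Computes `I(A;B|C)` from a three-dimensional array `p(a, b, c)` where the
#' conditioning variable is given by `cond_axis`. It is the
#' `p(c)`-weighted average of the per-condition mutual informations, hence
#' symmetric in the two non-conditioning axes.
#'
#' @param tab Numeric 3-d array summing to one.
#' @param cond_axis Which axis (1, 2 or 3) holds the conditioning variable.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(tab, cond_axis = 3L) {
  stopifnot(length(dim(tab)) == 3L)
  check_normalized(tab)
  perm <- c(setdiff(1:3, cond_axis), cond_axis)
  tab <- aperm(tab, perm)
  total <- 0
  for (k in seq_len(dim(tab)[3])) {
    slice <- tab[, , k, drop = FALSE]
    dim(slice) <- dim(tab)[1:2]
    pc <- sum(slice)
    if (pc > 0) total <- total + pc * mutual_information(slice / pc)
  }
  total
}
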