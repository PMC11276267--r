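#' Build the augmented (Y, S, Z) joint distribution
#'
#' Pools the source channels of a system into a single joint distribution over
#' the target `Y`, a source-identity variable `S` (which source produced the
#' outcome, drawn from `nu_s` independently of `Y`), and the pooled source
#' outcome `Z` whose alphabet is the union of the per-source output alphabets:
#' `p(y,s,z) = p(y) nu(s) p_{X_s|Y}(z|y)` for `z` in source `s`'s alphabet and
#' zero elsewhere. By construction `I(Y;S) = 0`.
#'
#' @param system An `rb_system`.
#' @return An object of class `rb_joint` with fields `y_outcomes`,
#'   `s_outcomes` (source names), `z_outcomes` (sorted union of source output
#'   alphabets), the probability array `p_ysz` indexed `[y, s, z]`, the logical
#'   `support` mask over `(s, z)` marking `z` in `X_s`, and the originating
#'   `system`.
#' @examples
#' jt <- build_joint(make_gate("unique"))
#' rate_bound(make_gate("unique"))
#' @export
build_joint <- function(system) {
  stopifnot(inherits(system, "rb_system"))
  y_out <- system$p_y$outcomes
  s_out <- names(system$sources)
  z_out <- sort(unique(unlist(lapply(system$sources, function(ch) ch$output_outcomes))))
  ny <- length(y_out); ns <- length(s_out); nz <- length(z_out)
  p_ysz <- array(0, dim = c(ny, ns, nz), dimnames = list(y_out, s_out, z_out))
  support <- matrix(FALSE, ns, nz, dimnames = list(s_out, z_out))
  for (s in seq_len(ns)) {
    ch <- system$sources[[s]]
    zi <- match(ch$output_outcomes, z_out)
    support[s, zi] <- TRUE
    p_ysz[, s, zi] <- system$p_y$probs * system$nu_s$probs[s] * ch$probs
  }
  structure(list(y_outcomes = y_out, s_outcomes = s_out, z_outcomes = z_out,
                 p_ysz = p_ysz, support = support, system = system),
            class = "rb_joint")
}

#' @export
print.rb_joint <- function(x, ...) {
  cat(sprintf("<rb_joint> |Y|=%d |S|=%d |Z|=%d, %d supported (s,z) pairs\n",
              length(x$y_outcomes), length(x$s_outcomes), length(x$z_outcomes),
              sum(x$support)))
  invisible(x)
}

#' Maximum achievable prediction, in bits
#'
#' The weighted-average source information `sum_s nu(s) I(X_s; Y)`, which
#' equals `I(Z; Y | S)` of the augmented joint and upper-bounds the bottleneck
#' prediction at every compression rate.
#'
#' @param system An `rb_system`.
#' @return Bits.
#' @export
prediction_bound <- function(system) {
  stopifnot(inherits(system, "rb_system"))
  vals <- vapply(system$sources, function(ch) {
    mutual_information(system$p_y$probs * ch$probs)
  }, numeric(1))
  sum(system$nu_s$probs * vals)
}

#' Maximum useful compression rate, in bits
#'
#' `I(Z; S | Y)` of the augmented joint: the conditional information the
#' pooled outcome carries about which source produced it. Compression rates
#' beyond this value cannot change the bottleneck solution.
#'
#' @param system An `rb_system`.
#' @return Bits.
#' @export
rate_bound <- function(system) {
  jt <- build_joint(system)
  conditional_mutual_information(aperm(jt$p_ysz, c(3, 2, 1)), cond_axis = 3L)
}

#' Per-source mutual informations `I(X_s; Y)` in bits
#'
#' @param system An `rb_system`.
#' @return Named numeric vector, one entry per source.
#' @export
source_informations <- function(system) {
  stopifnot(inherits(system, "rb_system"))
  vapply(system$sources, function(ch) {
    mutual_information(system$p_y$probs * ch$probs)
  }, numeric(1))
}
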