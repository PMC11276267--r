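#' Default logarithmic tradeoff grid
#'
#' Fifty logarithmically spaced values of the tradeoff parameter spanning
#' `1e-2` to `1e3`, which covers both the compression-dominated and the
#' prediction-dominated regime in all benchmark gates. The grid starts at a
#' small positive value rather than zero because the update rule degenerates
#' at `beta = 0`.
#'
#' @param beta_min,beta_max Positive endpoints.
#' @param n Number of grid points.
#' @return Increasing numeric vector.
#' @export
default_beta_grid <- function(beta_min = 1e-2, beta_max = 1e3, n = 50L) {
  stopifnot(beta_min > 0, beta_max > beta_min, n >= 1L)
  exp(seq(log(beta_min), log(beta_max), length.out = n))
}

#' Trace the redundancy bottleneck curve by annealing
#'
#' Solves the bottleneck problem at each tradeoff value of an increasing
#' grid, warm-starting every solve from the best channel found at the
#' previous (smaller) value in addition to `config$n_restarts` fresh random
#' restarts.
#'
#' @param joint An `rb_joint`.
#' @param beta_grid Strictly increasing vector of positive tradeoff values.
#' @param config A `solver_config`; its `beta` field is overridden by the
#'   grid.
#' @return An object of class `rb_curve`: the list of solved `rb_point`s (in
#'   grid order), the grid, a config snapshot and a fingerprint of the system.
#' @examples
#' crv <- anneal_curve(build_joint(make_gate("and")),
#'                     default_beta_grid(n = 5),
#'                     solver_config(n_restarts = 2, seed = 1))
#' rb_at_rate(crv, 0.1)
#' @export
anneal_curve <- function(joint, beta_grid = default_beta_grid(),
                         config = solver_config()) {
  stopifnot(inherits(joint, "rb_joint"))
  if (length(beta_grid) < 1L) stop("empty tradeoff grid", call. = FALSE)
  if (any(beta_grid <= 0) || any(diff(beta_grid) <= 0)) {
    stop("`beta_grid` must be strictly increasing and positive", call. = FALSE)
  }
  points <- vector("list", length(beta_grid))
  warm <- NULL
  for (k in seq_along(beta_grid)) {
    cfg <- config
    cfg$beta <- beta_grid[k]
    cfg$seed <- as.integer((config$seed + 7919L * k) %% .Machine$integer.max)
    pt <- solve_rb(joint, cfg, warm_start = warm)
    points[[k]] <- pt
    warm <- pt$r
  }
  structure(list(points = points, beta_grid = beta_grid, config = config,
                 fingerprint = joint_fingerprint(joint)),
            class = "rb_curve")
}

joint_fingerprint <- function(joint) {
  sprintf("|Y|=%d |S|=%d |Z|=%d mass=%.12f",
          length(joint$y_outcomes), length(joint$s_outcomes),
          length(joint$z_outcomes), sum(joint$p_ysz))
}

#' @export
print.rb_curve <- function(x, ...) {
  cat(sprintf("<rb_curve> %d points, beta in [%g, %g]\n",
              length(x$points), min(x$beta_grid), max(x$beta_grid)))
  invisible(x)
}

#' Achieved (compression, prediction) pairs of a curve
#'
#' @param curve An `rb_curve`.
#' @return Data frame with one row per tradeoff value: `beta`, `prediction`,
#'   `compression`, `objective`, `converged`, `n_iter`.
#' @export
curve_points <- function(curve) {
  stopifnot(inherits(curve, "rb_curve"))
  do.call(rbind, lapply(curve$points, function(p) {
    data.frame(beta = p$beta, prediction = p$prediction,
               compression = p$compression, objective = p$objective,
               converged = p$converged, n_iter = p$n_iter)
  }))
}

# Upper concave envelope of achieved (compression, prediction) pairs:
# sort by compression, drop dominated points, take the upper hull.
# Restart noise can produce dominated points; concavity of the true
# frontier licenses the hull.
concave_envelope <- function(comp, pred) {
  o <- order(comp, -pred)
  x <- comp[o]; y <- pred[o]
  keep <- !duplicated(x)  # best prediction per compression value
  x <- x[keep]; y <- y[keep]
  cm <- cummax(y)
  keep <- y >= cm - 1e-15  # dominated: lower prediction at higher compression
  x <- x[keep]; y <- y[keep]
  # Andrew-style upper hull
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_along(x)) {
    while (length(hx) >= 2) {
      n <- length(hx)
      cross <- (hx[n] - hx[n - 1]) * (y[i] - hy[n - 1]) -
               (x[i] - hx[n - 1]) * (hy[n] - hy[n - 1])
      if (cross >= 0) { hx <- hx[-n]; hy <- hy[-n] } else break
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  list(comp = hx, pred = hy)
}

#' Interpolated bottleneck value at a fixed compression rate
#'
#' Evaluates the prediction value of the upper concave envelope of the
#' achieved (compression, prediction) pairs, linearly interpolated at
#' compression `R`. For `R` at or beyond the largest achieved compression the
#' maximum achieved prediction is returned; below the smallest achieved
#' compression the first envelope point is used. The result is non-decreasing
#' and concave in `R` by construction.
#'
#' @param curve An `rb_curve` (or anything with at least one solved point).
#' @param R Compression rate in bits, `R >= 0`.
#' @return Prediction in bits.
#' @export
rb_at_rate <- function(curve, R) {
  stopifnot(inherits(curve, "rb_curve"))
  if (length(curve$points) < 1L) stop("curve has no points", call. = FALSE)
  stopifnot(is.numeric(R), all(R >= 0))
  pts <- curve_points(curve)
  env <- concave_envelope(pts$compression, pts$prediction)
  vapply(R, function(r) {
    if (r <= env$comp[1]) return(env$pred[1])
    if (r >= env$comp[length(env$comp)]) return(env$pred[length(env$pred)])
    stats::approx(env$comp, env$pred, xout = r, ties = "ordered")$y
  }, numeric(1))
}

#' Per-source bottleneck traces
#'
#' Extracts, for every solved point, each source's specific conditional
#' mutual informations: its prediction contribution `I(Q;Y|S=s)` and
#' compression contribution `I(Q;S=s|Y)`. Unlike the overall curve, the
#' per-source traces may be non-concave and non-monotonic.
#'
#' @param curve An `rb_curve`.
#' @return Data frame with columns `source`, `beta`, `weight`, `pred_s`,
#'   `comp_s`.
#' @export
per_source_curves <- function(curve) {
  stopifnot(inherits(curve, "rb_curve"))
  do.call(rbind, lapply(curve$points, function(p) {
    cbind(beta = p$beta, p$per_source)
  }))[, c("source", "beta", "weight", "pred_s", "comp_s")]
}
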