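test_that("distribution and channel constructors enforce their invariants", {
  expect_error(discrete_dist(c(0.6, 0.6)), "sum")
  expect_error(discrete_dist(c(1.2, -0.2)), "nonnegative")
  expect_error(discrete_dist(c(0.5, 0.5), c("a", "a")), "duplicate")
  expect_error(channel(rbind(c(0.5, 0.4), c(0.5, 0.5))), "sum to 1")
  expect_error(channel(rbind(c(1.5, -0.5), c(0.5, 0.5))), "nonnegative")
  # full-support requirements on the system
  y0 <- discrete_dist(c(1, 0), c("0", "1"))
  expect_error(source_system(y0, list(channel(diag(2)))), "full support")
  yu <- discrete_dist(c(0.5, 0.5), c("0", "1"))
  ch2 <- channel(diag(2), c("0", "1"))
  expect_error(source_system(yu, list(ch2, ch2), nu_s = c(1, 0)), "full support")
  ch3 <- channel(matrix(1 / 3, 2, 3), c("a", "b"))
  expect_error(source_system(yu, list(ch3)), "alphabet")
})

test_that("entropy and KL divergence match hand-computed values", {
  expect_equal(entropy(discrete_dist(c(0.5, 0.5))), 1.0)
  expect_equal(entropy(c(1, 0)), 0.0)
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0.0)
  # direct evaluation of sum p log2(p/q)
  expect_equal(kl_divergence(c(3 / 4, 1 / 4), c(1 / 2, 1 / 2)),
               0.75 * log2(1.5) + 0.25 * log2(0.5), tolerance = 1e-14)
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  expect_gt(kl_divergence(c(0.9, 0.1), c(0.5, 0.5)), 0)
})

test_that("mutual information agrees with a term-by-term oracle on random joints", {
  for (seed in 1:5) {
    set.seed(seed)
    tab <- array(rexp(27), dim = c(3, 3, 3))
    tab <- tab / sum(tab)
    two <- apply(tab, c(1, 2), sum)
    expect_equal(mutual_information(two), mi_oracle(two), tolerance = 1e-10)
    expect_equal(conditional_mutual_information(tab, 3), cmi_oracle(tab),
                 tolerance = 1e-10)
    # symmetry in the two non-conditioning axes
    expect_equal(conditional_mutual_information(tab, 3),
                 conditional_mutual_information(aperm(tab, c(2, 1, 3)), 3),
                 tolerance = 1e-12)
    expect_gte(conditional_mutual_information(tab, 1), 0)
  }
  expect_error(mutual_information(matrix(0.4, 2, 2)), "sums to")
})

test_that("channel composition follows symmetric-channel algebra", {
  bsc <- function(e) channel(rbind(c(1 - e, e), c(e, 1 - e)), c("0", "1"), c("0", "1"))
  idc <- channel(diag(2), c("0", "1"), c("0", "1"))
  expect_equal(compose_channels(idc, bsc(0.2))$probs, bsc(0.2)$probs)
  a <- 0.1; e <- 0.25
  expect_equal(compose_channels(bsc(a), bsc(e))$probs,
               bsc(a * (1 - e) + (1 - a) * e)$probs, tolerance = 1e-14)
  const <- channel(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE), c("0", "1"), c("u", "v"))
  expect_equal(compose_channels(const, bsc(0.3))$probs, const$probs)
  expect_error(compose_channels(bsc(0.1), const), "mismatch")
})

test_that("augmented joint has the product form, correct support and I(Y;S)=0", {
  jt <- fixture_joint("unique")
  expect_equal(jt$p_ysz["0", "X1", "0"], 0.25)
  expect_equal(sum(jt$p_ysz), 1, tolerance = 1e-14)
  # zero outside the per-source support
  for (s in seq_along(jt$s_outcomes)) {
    expect_true(all(jt$p_ysz[, s, !jt$support[s, ]] == 0))
  }
  ja <- fixture_joint("and")
  expect_equal(ja$p_ysz["1", "X1", "1"], 0.125)
  expect_equal(ja$p_ysz["1", "X2", "1"], 0.125)
  # marginals recover p_y and nu_s exactly
  expect_equal(apply(ja$p_ysz, 1, sum), c(3 / 4, 1 / 4),
               ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(apply(ja$p_ysz, 2, sum), c(0.5, 0.5),
               ignore_attr = TRUE, tolerance = 1e-14)
  for (seed in 1:4) {
    sys <- random_system(n_sources = 3, y_card = 3, x_cards = c(2, 3, 4), seed = seed)
    j <- build_joint(sys)
    ys <- apply(j$p_ysz, c(1, 2), sum)
    expect_lt(mutual_information(ys), 1e-10)
    expect_equal(apply(j$p_ysz, 1, sum), sys$p_y$probs,
                 ignore_attr = TRUE, tolerance = 1e-14)
  }
  # single-source system: p(y,1,z) = p(y) p(x|y)
  one <- source_system(discrete_dist(c(0.3, 0.7), c("0", "1")),
                       list(X1 = channel(rbind(c(0.8, 0.2), c(0.4, 0.6)),
                                         c("0", "1"), c("0", "1"))))
  j1 <- build_joint(one)
  expect_equal(sum(j1$p_ysz), 1, tolerance = 1e-14)
  expect_equal(j1$p_ysz["0", "X1", "0"], 0.3 * 0.8)
})

test_that("relabeling source outcomes leaves the bottleneck solution unchanged", {
  # swap the labels of X2's outcomes (a within-alphabet permutation)
  y <- discrete_dist(c(0.5, 0.5), c("0", "1"))
  x1 <- channel(diag(2), c("0", "1"), c("0", "1"))
  x2_swapped <- channel(matrix(0.5, 2, 2), c("0", "1"), c("1", "0"))
  sys2 <- source_system(y, list(X1 = x1, X2 = x2_swapped))
  expect_equal(rate_bound(sys2), rate_bound(fixture_system("unique")),
               tolerance = 1e-12)
  # disjoint relabeling changes Z but not the optimal tradeoff point
  x2_disjoint <- channel(matrix(0.5, 2, 2), c("0", "1"), c("a", "b"))
  sys3 <- source_system(y, list(X1 = x1, X2 = x2_disjoint))
  pt <- solve_rb(build_joint(sys3), solver_config(beta = 1000, seed = 5))
  expect_equal(pt$prediction, 0.5, tolerance = 1e-3)
  expect_equal(pt$compression, rate_bound(fixture_system("unique")), tolerance = 1e-3)
})

test_that("prediction and rate bounds reproduce the benchmark values", {
  u <- fixture_system("unique")
  expect_equal(prediction_bound(u), 0.5, tolerance = 1e-12)
  expect_equal(rate_bound(u), entropy(c(0.75, 0.25)) - 0.5, tolerance = 1e-12)
  mi <- source_informations(u)
  expect_equal(unname(mi), c(1, 0), tolerance = 1e-12)
  s <- fixture_system("spin_overlap")
  expect_equal(prediction_bound(s), 2, tolerance = 1e-12)
  expect_equal(rate_bound(s), 0.5 * entropy(c(2 / 3, 1 / 3)), tolerance = 1e-12)
  # one-source system: S is constant, so the rate bound vanishes
  one <- source_system(discrete_dist(c(0.5, 0.5), c("0", "1")),
                       list(channel(diag(2), c("0", "1"))))
  expect_equal(rate_bound(one), 0, tolerance = 1e-12)
  # decomposition identity: I(Z;Y|S) = sum_s nu(s) I(X_s;Y)
  for (seed in 1:3) {
    sys <- random_system(2, 3, 3, seed = seed)
    j <- build_joint(sys)
    expect_equal(conditional_mutual_information(aperm(j$p_ysz, c(3, 1, 2)), 3),
                 prediction_bound(sys), tolerance = 1e-12)
  }
})
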