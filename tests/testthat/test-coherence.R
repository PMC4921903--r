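tt7 <- c(0, 2.5, 5, 10, 20, 40, 80)

test_that("profile difference matches the textbook Pearson oracle", {
  expect_equal(profile_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(profile_difference(c(1, 2, 3), c(3, 2, 1)), 0)   # |r| of -1
  expect_equal(profile_difference(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.2)
  set.seed(17)
  for (i in 1:100) {
    a <- rnorm(7); b <- rnorm(7)
    expect_lt(abs(profile_difference(a, b) - profile_difference_oracle(a, b)), 1e-12)
    expect_lt(abs(magnitude_difference(a, b) - magnitude_difference_oracle(a, b)), 1e-12)
  }
})

test_that("degenerate profiles yield an explicit undefined result", {
  d <- profile_difference(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(d))
  expect_match(attr(d, "reason"), "constant")
  expect_error(profile_difference(c(1, 2), c(1, 2)), "length")
})

test_that("magnitude difference is the absolute gap of Euclidean norms", {
  expect_equal(magnitude_difference(c(3, 4), c(3, 4)), 0)
  expect_equal(magnitude_difference(c(3, 4), c(0, 0)), 5)
  expect_equal(magnitude_difference(c(3, 4), c(6, 8)), 5)
})

test_that("d is affine-invariant and bounded; m is scale-sensitive", {
  set.seed(18)
  for (i in 1:50) {
    a <- rnorm(7); b <- rnorm(7)
    al <- runif(1, 0.2, 3) * sample(c(-1, 1), 1); be <- rnorm(1)
    expect_equal(profile_difference(al * a + be, b), profile_difference(a, b))
    d <- profile_difference(a, b)
    expect_true(d >= 0 && d <= 1)
    expect_gte(magnitude_difference(a, b), 0)
  }
  a <- c(1, 2, 3, 5, 2, 1, 0)
  expect_false(isTRUE(all.equal(magnitude_difference(2 * a, a),
                                magnitude_difference(a, a))))
  expect_equal(profile_difference(a, a), 0)
  expect_equal(magnitude_difference(a, a), 0)
})

test_that("quadrants split at the thresholds with ties going high", {
  expect_equal(classify_quadrant(0, 0, 0.5, 1), "lower-left")
  expect_equal(classify_quadrant(0.8, 2, 0.5, 1), "upper-right")
  expect_equal(classify_quadrant(0.5, 0, 0.5, 1), "lower-right")   # boundary d
  expect_equal(classify_quadrant(0.2, 1, 0.5, 1), "upper-left")    # boundary m
  expect_equal(classify_quadrant(0.9, 0.2, 0.5, 1), "lower-right")
  expect_equal(classify_quadrant(NA, 3, 0.5, 1), "undefined")
})

test_that("identical draw pairs give zero-width intervals and no omission", {
  draws <- make_corr_draws(rep(0.6, 400))
  cp <- coherence_point(draws$A, draws$B, "tf1")
  expect_equal(cp$d_lo95, cp$d_hi95)
  expect_false(cp$omitted)
  expect_equal(cp$profile_difference, 0.4, tolerance = 1e-12)
})

test_that("the +/-0.15 omission rule triggers exactly above half-width 0.15", {
  # two-point |r| distributions with prescribed interval half-widths
  half <- function(h) c(rep(0.6 - h, 500), rep(0.6 + h, 500))
  narrow <- make_corr_draws(half(0.10))
  wide <- make_corr_draws(half(0.20))
  at_rule <- make_corr_draws(half(0.15))
  cp_narrow <- coherence_point(narrow$A, narrow$B, "tf1")
  cp_wide <- coherence_point(wide$A, wide$B, "tf1")
  cp_at <- coherence_point(at_rule$A, at_rule$B, "tf1")
  expect_false(cp_narrow$omitted)
  expect_true(cp_wide$omitted)
  expect_false(cp_at$omitted)          # "greater than" is strict
  expect_equal((cp_narrow$d_hi95 - cp_narrow$d_lo95) / 2, 0.10)
  expect_equal((cp_wide$d_hi95 - cp_wide$d_lo95) / 2, 0.20)
})

test_that("point estimates agree with the direct statistics on mean profiles", {
  set.seed(19)
  mkpost <- function() {
    draws <- array(rnorm(300 * 2 * 7, sd = 0.3), c(300, 2, 7))
    for (m in 1:2) draws[, m, ] <- sweep(draws[, m, ], 2,
                                         rnorm(7, sd = 1), `+`)
    tfa_posterior(draws, c("tfA", "tfB"), tt7)
  }
  pa <- mkpost(); pb <- mkpost()
  cp <- coherence_point(pa, pb, "tfA")
  expect_equal(cp$profile_difference,
               profile_difference(pa$mean["tfA", ], pb$mean["tfA", ]))
  expect_equal(cp$magnitude_difference,
               magnitude_difference(pa$mean["tfA", ], pb$mean["tfA", ]))
  tab <- coherence_table(pa, pb)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("profile_difference", "magnitude_difference", "omitted",
                    "quadrant") %in% names(tab)))
  # mismatched grids are a hard error
  pb2 <- tfa_posterior(pb$draws, pb$tf_ids, tt7 + 1)
  expect_error(coherence_point(pa, pb2, "tfA"), "grid")
  pc <- tfa_posterior(pa$draws, c("x1", "x2"), tt7)
  expect_error(coherence_table(pa, pc), "share no TFs")
})

test_that("default magnitude threshold is the median over usable TFs", {
  set.seed(20)
  draws <- array(rnorm(200 * 3 * 7, sd = 0.05), c(200, 3, 7))
  base <- rbind(sin(1:7), cos(1:7), (1:7) / 4)
  for (m in 1:3) draws[, m, ] <- sweep(draws[, m, ], 2, base[m, ], `+`)
  pa <- tfa_posterior(draws, paste0("tf", 1:3), tt7)
  pb <- tfa_posterior(draws * 2, paste0("tf", 1:3), tt7)
  tab <- coherence_table(pa, pb)
  ok <- !tab$omitted & !is.na(tab$profile_difference)
  expect_equal(attr(tab, "m_threshold"), median(tab$magnitude_difference[ok]))
})

test_that("95% intervals for d cover the true value in most trials", {
  set.seed(22)
  a0 <- eval_shape(activity_shape("transient_pulse", 2, 10), tt7)
  b0 <- 0.6 * a0 + 0.8 * eval_shape(activity_shape("monotone_rise", 2), tt7)
  d0 <- profile_difference(a0, b0)
  n_draws <- 300
  hits <- 0
  for (trial in 1:200) {
    A <- array(rep(a0, each = n_draws) + rnorm(n_draws * 7, 0, 0.1), c(n_draws, 1, 7))
    B <- array(rep(b0, each = n_draws) + rnorm(n_draws * 7, 0, 0.1), c(n_draws, 1, 7))
    cp <- coherence_point(tfa_posterior(A, "tf1", tt7),
                          tfa_posterior(B, "tf1", tt7), "tf1", seed = trial)
    hits <- hits + (cp$d_lo95 <= d0 && d0 <= cp$d_hi95)
  }
  expect_gte(hits, 180)   # >= 90% of 200 constructed trials
})
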