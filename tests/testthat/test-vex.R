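# straight-line reimplementation of the circular-variance-explained
# formulas, kept deliberately independent of the package internals
vex_oracle <- function(phase, cond) {
  conds <- sort(unique(cond))
  N <- length(phase)
  Vw_parts <- 0
  for (j in conds) {
    th <- phase[cond == j]
    Nj <- length(th)
    Vjw <- 1 - Mod(sum(exp(1i * th)) / Nj)
    Vw_parts <- Vw_parts + Nj * Vjw
  }
  Vw <- Vw_parts / N
  Va <- 1 - Mod(sum(exp(1i * phase)) / N)
  1 - Vw / Va
}

test_that("vex matches an independent straight-line implementation", {
  ph <- c(0.3, 0.5, 0.4, 0.45, 2.0, 2.2, 1.9, 2.1)
  cd <- rep(1:2, each = 4)
  s <- phase_sample_set(ph, cd)
  expect_equal(vex(s)$Vex, vex_oracle(ph, cd))

  set.seed(5)
  for (i in 1:10) {
    ph <- runif(40, 0, 2 * pi)
    cd <- sample(1:4, 40, replace = TRUE)
    if (min(table(cd)) < 2 || length(unique(cd)) < 2) next
    expect_equal(vex(phase_sample_set(ph, cd))$Vex, vex_oracle(ph, cd))
  }
})

test_that("perfect separation gives Vw = 0, Vex = 1; labels carry no
          information in the null limit", {
  s <- phase_sample_set(rep(c(0.2, 1.7, 3.1, 4.6), each = 3),
                        rep(1:4, each = 3))
  v <- vex(s)
  expect_equal(v$Vw, 0)
  expect_equal(v$Vex, 1)

  set.seed(6)
  vals <- vapply(1:200, function(i) {
    vex(phase_sample_set(rvonmises(200, 1, 1.5),
                         rep(1:4, each = 50)))$Vex
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)  # ~0 in expectation under the null
})

test_that("vex is invariant under global phase rotation", {
  set.seed(7)
  ph <- runif(60, 0, 2 * pi)
  cd <- rep(1:4, each = 15)
  v0 <- vex(phase_sample_set(ph, cd))$Vex
  for (rot in c(0.5, 2, 5)) {
    expect_equal(vex(phase_sample_set(ph + rot, cd))$Vex, v0)
  }
})

test_that("vex rejects degenerate inputs", {
  expect_error(vex(phase_sample_set(c(1, 1, 1, 1), c(1, 1, 2, 2))),
               "undefined")
  expect_error(vex(phase_sample_set(c(1, 2, 3), c(1, 1, 2))), "conditions")
})

test_that("permutation p-value honors the add-one floor and detects planted
          separation", {
  s <- planted_phase_set(c(0, pi / 2, pi, 3 * pi / 2), kappa = 8,
                        n_per = 10, seed = 3)
  vt <- vex_permutation_test(s, n_perm = 199L, seed = 1)
  expect_equal(vt$p, 1 / 200)  # observed exceeds every null draw

  # majority of units with kappa = 2 separation are detected at alpha=.05
  det <- vapply(1:40, function(i) {
    s <- planted_phase_set(c(0, pi / 2, pi, 3 * pi / 2), kappa = 2,
                          n_per = 28, seed = 100 + i)
    vex_permutation_test(s, n_perm = 199L, seed = i,
                         keep_null = FALSE)$p < 0.05
  }, logical(1))
  expect_gt(mean(det), 0.5)
})

test_that("permutation null p-values are uniform under no effect", {
  set.seed(8)
  ps <- vapply(1:300, function(i) {
    s <- phase_sample_set(runif(40, 0, 2 * pi), rep(1:4, each = 10))
    vex_permutation_test(s, n_perm = 99L, seed = i, keep_null = FALSE)$p
  }, numeric(1))
  # p-values are discrete (ties expected); the KS statistic is still a
  # fair uniformity check at this resolution
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("exhaustive enumeration is used for tiny samples", {
  s <- phase_sample_set(c(0.1, 0.2, 2.1, 2.2), c(1, 1, 2, 2))
  expect_warning(vt <- vex_permutation_test(s, n_perm = 1999L),
                 "exhaustively")
  expect_true(vt$exact)
  expect_equal(vt$n_perm, 6L)  # 4!/(2!2!) = 6 relabelings
})

test_that("two-frequency significance rule aggregates correctly", {
  expect_true(unit_significant(c(0.01, 0.2, 0.03, 0.8)))
  expect_false(unit_significant(c(0.01, 0.2, 0.3, 0.8)))
  expect_false(unit_significant(c(NA, 0.01, NA, 0.6)))
})

test_that("Hedges g matches the textbook formula and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  # pooled sd = 1, d = -1, correction 1 - 3/(4*4 - 1) = 0.8
  expect_equal(hedges_g(a, b), -0.8)
  expect_equal(hedges_g(b, a), 0.8)
  expect_equal(hedges_g(a, a), 0)
  expect_error(hedges_g(c(1, 1, 1), c(1, 1, 1)), "variance")
})

test_that("bootstrap proportion CI behaves at the edges and covers", {
  all_sig <- bootstrap_proportion(rep(TRUE, 20), n_boot = 200L)
  expect_equal(all_sig$ci, c(1, 1))

  single <- bootstrap_proportion(TRUE, n_boot = 50L)
  expect_true(single$degenerate)

  # coverage: CI contains the true proportion in ~95% of meta-replicates
  set.seed(9)
  cover <- vapply(1:200, function(i) {
    x <- runif(100) < 0.3
    ci <- bootstrap_proportion(x, n_boot = 199L, seed = i)$ci
    ci[1] <= 0.3 && 0.3 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.88)
})

test_that("Simes correction applies the stepwise rule", {
  r <- simes_correct(c(0.01, 0.02, 0.03))
  expect_true(all(r$reject))
  expect_false(any(simes_correct(rep(1, 5))$reject))
  one <- simes_correct(0.04)
  expect_equal(one$adjusted, 0.04)
  expect_true(one$reject)
  expect_error(simes_correct(c(0, 0.5)), "lie in")
})

test_that("rate-matched subsampling equalizes counts and keeps uniformity", {
  a <- 1:100; b <- 1:40
  r <- rate_matched_subsample(a, b, seed = 2)
  expect_equal(length(r$a), 40L)
  expect_equal(length(r$b), 40L)
  expect_identical(r$b, b)

  same <- rate_matched_subsample(1:10, 11:20)
  expect_identical(same$a, 1:10)

  # calibration: subsampled uniform phases stay uniform
  set.seed(10)
  ps <- vapply(1:100, function(i) {
    ph <- runif(300, 0, 2 * pi)
    sub <- rate_matched_subsample(ph, runif(80, 0, 2 * pi), seed = i)
    rayleigh_test(sub$a)$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.12)
})
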