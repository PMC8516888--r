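test_that("pearson handles perfect, hand-computable, and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  r1 <- pearson(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-10)
  expect_equal(pearson(x, -x)$r, -1)

  # product-moment arithmetic by hand: x=(1,2,3,4), y=(1,3,2,4) -> r = 0.8
  r <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  expect_equal(r$p, 2 * pt(-0.8 * sqrt(2) / 0.6, df = 2))

  expect_error(pearson(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("paired t test matches hand arithmetic, stars, and degenerate guards", {
  # x=(1,2,3), y=(2,3,5): d=(-1,-1,-2), mean -4/3, sd 1/sqrt(3), t = -4
  tt <- paired_ttest(c(1, 2, 3), c(2, 3, 5))
  expect_equal(tt$t, -4)
  expect_equal(tt$p, 2 * pt(-4, df = 2))
  expect_identical(tt$stars, "ns")

  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)), "degenerate")

  jit <- paired_ttest(c(1, 1, 1, 1.0001), c(0, 0, 0, 0))
  expect_gt(abs(jit$t), 100)
  expect_lt(jit$p, 0.001)
  expect_identical(jit$stars, "***")

  expect_identical(stars_for_p(0.04), "*")
  expect_identical(stars_for_p(0.009), "**")
  expect_identical(stars_for_p(0.2), "ns")
})

test_that("implementation agrees with first-principles sums on random vectors", {
  set.seed(1234)
  for (i in seq_len(25)) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    bf <- pearson_bf(x, y)
    im <- pearson(x, y)
    expect_lt(abs(im$r - bf$r) / max(abs(bf$r), 1e-12), 1e-10)
    expect_lt(abs(im$p - bf$p) / max(bf$p, 1e-300), 1e-8)
    bt <- paired_ttest_bf(x, y)
    it <- paired_ttest(x, y)
    expect_lt(abs(it$t - bt$t) / max(abs(bt$t), 1e-12), 1e-10)
  }
})

test_that("replicate summaries use the sample sd and declare n = 1 sd missing", {
  expect_equal(summarize_reps(c(2, 2, 2)), list(mean = 2, sd = 0, n = 3L))
  expect_equal(summarize_reps(c(1, 2, 3)), list(mean = 2, sd = 1, n = 3L))
  s1 <- summarize_reps(5)
  expect_identical(s1$mean, 5)
  expect_true(is.na(s1$sd))
  expect_error(summarize_reps(numeric(0)), "no values")
})

test_that("the correlation matrix is symmetric with a unit diagonal", {
  exp0 <- generate_experiment(render = FALSE, field_ref = ref_field(),
                              master_seed = 3L)
  cm <- correlation_heatmap(exp0$measurements)
  expect_identical(cm$r, t(cm$r))
  expect_true(all(diag(cm$r) == 1))
  expect_true(all(diag(cm$p) == 0))
  expect_identical(dim(cm$r), c(5L, 5L))
  tab <- correlation_table(cm)
  expect_identical(nrow(tab), 25L)
  expect_error(correlation_heatmap(exp0$measurements[1:2, ]), "at least 3")
})

test_that("condition-level aggregation averages replicates before correlating", {
  exp0 <- generate_experiment(render = FALSE, field_ref = ref_field(),
                              master_seed = 3L)
  cm <- correlation_heatmap(exp0$measurements, aggregate = "condition")
  expect_true(all(cm$n[upper.tri(cm$n)] == 5))
  expect_true(all(abs(cm$r[upper.tri(cm$r)]) <= 1))
})
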