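test_that("all four estimators match brute-force oracles on random series", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(60:200, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, m = 2, r = r), apen_oracle(x, 2, r),
                 tolerance = 1e-9)
    se_o <- sampen_oracle(x, 2, r)
    if (!is.na(se_o))
      expect_equal(sample_entropy(x, m = 2, r = r), se_o, tolerance = 1e-9)
    expect_equal(permutation_entropy(x, D = 3), pen_oracle(x, 3),
                 tolerance = 1e-9)
    expect_equal(state_space_correlation_entropy(x, D = 3, K = 8),
                 sscen_oracle(x, 3, 8), tolerance = 1e-9)
  }
})

test_that("ApEn closed cases: constant and alternating series", {
  expect_equal(approximate_entropy(rep(3, 50), m = 2, r = 0.2), 0)
  x <- rep(c(1, -1), 25)
  expect_equal(approximate_entropy(x, m = 2, r = 0.5),
               apen_oracle(x, 2, 0.5), tolerance = 1e-9)
})

test_that("SampEn: constant series gives 0; periodic input is length-free", {
  expect_equal(sample_entropy(rep(2, 40), m = 2, r = 0.1), 0)
  p100 <- sample_entropy(rep(c(1, 2), 50), m = 2, r = 0.3)
  p400 <- sample_entropy(rep(c(1, 2), 200), m = 2, r = 0.3)
  expect_equal(p100, p400, tolerance = 1e-9)
  expect_equal(p100, 0)
})

test_that("SampEn signals undefined rather than returning a large value", {
  set.seed(99)
  x <- rnorm(30)
  expect_error(sample_entropy(x, m = 2, r = 1e-9), class = "emodyn_undefined")
})

test_that("PEn closed cases: monotone series and the 7-point worked example", {
  expect_equal(permutation_entropy(1:50, D = 3), 0)
  expect_equal(permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), D = 2),
               0.9182958, tolerance = 1e-6)
})

test_that("PEn of long uniform noise approaches its upper bound log2(D!)", {
  set.seed(123)
  x <- runif(1e5)
  expect_equal(permutation_entropy(x, D = 3), log2(6), tolerance = 0.05)
})

test_that("SSCEn degenerate cases: constant series and a single bin", {
  expect_equal(state_space_correlation_entropy(rep(5, 40), D = 3, K = 8), 0)
  set.seed(8)
  expect_equal(state_space_correlation_entropy(rnorm(40), D = 3, K = 1), 0)
})

test_that("SSCEn on a fixed normal draw equals the independent oracle", {
  set.seed(2024)
  x <- rnorm(500)
  expect_equal(state_space_correlation_entropy(x, D = 3, K = 8),
               sscen_oracle(x, 3, 8), tolerance = 1e-12)
})

test_that("estimators are invariant under positive affine transforms", {
  set.seed(31)
  x <- rnorm(150)
  y <- 3.2 * x + 11
  expect_equal(approximate_entropy(x), approximate_entropy(y), tolerance = 1e-9)
  expect_equal(sample_entropy(x), sample_entropy(y), tolerance = 1e-9)
  expect_equal(permutation_entropy(x), permutation_entropy(y), tolerance = 1e-12)
  expect_equal(state_space_correlation_entropy(x),
               state_space_correlation_entropy(y), tolerance = 1e-9)
})

test_that("entropy upper bounds hold across random inputs", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(120)
    expect_lte(permutation_entropy(x, D = 3), log2(factorial(3)))
    expect_lte(state_space_correlation_entropy(x, D = 3, K = 16), log2(16))
  }
})

test_that("sliding windows tile the series and respect estimator minima", {
  fs <- 20
  set.seed(41)
  X <- matrix(rnorm(2 * 300 * fs), 2)
  rownames(X) <- c("a", "b")
  fser <- sliding_feature_series(X, estimators = "pen",
                                 params = entropy_params(window = 5), fs = fs)
  expect_equal(dim(fser$values), c(60, 2, 1))
  expect_equal(fser$timestamps[1:3], c(0, 5, 10))
  expect_error(sliding_feature_series(X[, 1:50, drop = FALSE],
                                      params = entropy_params(window = 5),
                                      fs = fs), "shorter than one window")
})

test_that("a constant signal yields an all-zero ApEn series", {
  X <- matrix(1, 1, 400)
  fser <- sliding_feature_series(X, estimators = "apen",
                                 params = entropy_params(window = 5), fs = 20)
  expect_true(all(fser$values == 0))
})

test_that("permuting channels permutes the feature series identically", {
  set.seed(42)
  X <- matrix(rnorm(3 * 200), 3)
  rownames(X) <- c("a", "b", "c")
  f1 <- sliding_feature_series(X, estimators = c("pen", "sscen"),
                               params = entropy_params(window = 2), fs = 50)
  f2 <- sliding_feature_series(X[c(2, 3, 1), ], estimators = c("pen", "sscen"),
                               params = entropy_params(window = 2), fs = 50)
  expect_equal(f1$values[, c("b", "c", "a"), ], f2$values[, , ])
})
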