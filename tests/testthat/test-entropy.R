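test_that("perfectly repeatable series have sample entropy exactly zero", {
  s <- sample_entropy(rep(5, 100))
  expect_identical(s$value, 0)
  expect_identical(s$a_count, s$b_count)

  alt <- sample_entropy(rep(c(0, 1), 100))
  expect_identical(alt$value, 0)

  o <- sample_entropy_oracle(rep(5, 100))
  expect_identical(o$value, 0)
  expect_identical(sample_entropy_oracle(rep(c(0, 1), 50))$value, 0)
})

test_that("optimized counts equal the brute-force oracle exactly", {
  set.seed(101)
  for (k in 1:12) {
    n <- sample(30:600, 1)
    x <- switch(1 + k %% 3,
                runif(n),
                cumsum(rnorm(n)),
                sin(seq_len(n) / 3) + rnorm(n, 0, 0.3))
    pars <- sampen_params(sample(2:3, 1), sample(c(0.15, 0.2, 0.25), 1))
    a <- tryCatch(suppressWarnings(sample_entropy(x, pars)),
                  error = function(e) "undefined")
    b <- tryCatch(suppressWarnings(sample_entropy_oracle(x, pars)),
                  error = function(e) "undefined")
    if (identical(a, "undefined") || identical(b, "undefined")) {
      # both paths must agree that entropy is undefined (B = 0)
      expect_identical(a, b)
    } else {
      expect_identical(as.integer(a$a_count), as.integer(b$a_count))
      expect_identical(as.integer(a$b_count), as.integer(b$b_count))
      expect_equal(a$value, b$value)
    }
  }
})

test_that("SampEn is invariant under affine rescaling", {
  set.seed(8)
  x <- runif(800)
  base <- sample_entropy(x)
  for (ab in list(c(3.5, 0), c(-2, 1.7), c(0.01, -5))) {
    s <- sample_entropy(ab[1] * x + ab[2])
    expect_identical(s$b_count, base$b_count)
    expect_equal(s$value, base$value, tolerance = 1e-12)
  }
})

test_that("SampEn is non-increasing in the tolerance r", {
  set.seed(15)
  x <- cumsum(rnorm(600))
  grid <- sampen_sensitivity(x, m_values = 3,
                             r_values = c(0.1, 0.15, 0.2, 0.3, 0.5))
  expect_true(all(diff(grid$sampen) <= 1e-12))
  # counts themselves are monotone: a larger radius admits all matches
  expect_true(all(diff(grid$b_count) >= 0))
  expect_true(all(diff(grid$a_count) >= 0))
})

test_that("value and count invariants hold on random series", {
  set.seed(23)
  for (k in 1:20) {
    x <- rnorm(sample(50:300, 1))
    s <- tryCatch(suppressWarnings(sample_entropy(x)),
                  error = function(e) NULL)  # B = 0: undefined, no claim
    if (is.null(s)) next
    expect_lte(s$a_count, s$b_count)
    expect_gte(s$value, 0)
  }
})

test_that("sensitivity grid covers the full m x r cardinality", {
  x <- generate_signal(signal_model("mix", p = 0.3, seed = 5), 400)
  grid <- sampen_sensitivity(x, m_values = c(2, 3),
                             r_values = c(0.15, 0.2, 0.25))
  expect_identical(nrow(grid), 6L)
  const_grid <- sampen_sensitivity(rep(2, 100), m_values = c(2, 3),
                                   r_values = c(0.15, 0.2, 0.25))
  expect_true(all(const_grid$sampen == 0))
})

test_that("degenerate match counts hit the documented sentinels", {
  # frozen examples (m = 2, r = 0.2): no (m+1)-matches -> +Inf with warning
  expect_warning(sinf <- sample_entropy(c(4, 1, 2, 2, 2, 4),
                                        sampen_params(2, 0.2)), "\\+Inf")
  expect_identical(sinf$value, Inf)
  expect_gt(sinf$b_count, 0)
  # no m-matches at all -> undefined entropy
  expect_error(sample_entropy(c(1, 0, 1, 1, 2, 1), sampen_params(2, 0.2)),
               "undefined")
  # oracle agrees on both edge cases
  expect_warning(oinf <- sample_entropy_oracle(c(4, 1, 2, 2, 2, 4),
                                               sampen_params(2, 0.2)))
  expect_identical(oinf$value, Inf)
  expect_error(sample_entropy_oracle(c(1, 0, 1, 1, 2, 1),
                                     sampen_params(2, 0.2)), "undefined")
})

test_that("length and parameter contracts are enforced", {
  expect_error(sample_entropy(1:4, sampen_params(3)), "exceed m \\+ 1")
  expect_error(sample_entropy_oracle(rnorm(6000)), "5000")
  expect_error(sampen_params(0), "m")
  expect_error(sampen_params(3, 0), "r")
})
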