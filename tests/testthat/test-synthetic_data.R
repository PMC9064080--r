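test_that("signal generation is deterministic under a fixed seed", {
  m <- signal_model("mix", p = 0.4, seed = 77)
  expect_identical(generate_signal(m, 500), generate_signal(m, 500))
  d <- cohort_design(seed = 5)
  r1 <- generate_trial(d, "B03", "AT", 2)
  r2 <- generate_trial(d, "B03", "AT", 2)
  expect_identical(r1$channels, r2$channels)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_signal(m, 100)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("MIX endpoints bracket the regularity scale", {
  pure <- generate_signal(signal_model("mix", p = 0, seed = 1), 1500)
  s0 <- sample_entropy(pure)
  expect_lte(s0$value, 0.05)

  noise <- generate_signal(signal_model("mix", p = 1, seed = 2), 1500)
  s1 <- sample_entropy(noise)
  # i.i.d. reference value from the brute-force oracle on a fresh
  # uniform draw of the same length and scale
  set.seed(3)
  ref <- sample_entropy_oracle(runif(1500))
  expect_lt(abs(s1$value - ref$value), 0.25)
  expect_gt(s1$value, 1.5)
})

test_that("mean SampEn is monotone in the MIX irregularity p", {
  ps <- seq(0, 1, by = 0.2)
  reps <- 8
  mean_se <- vapply(ps, function(p) {
    mean(vapply(seq_len(reps), function(k) {
      x <- generate_signal(signal_model("mix", p = p, seed = 1000 * k + p * 100),
                           1500)
      sample_entropy(x)$value
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(ps, mean_se, method = "spearman"), 0.9)
  expect_true(all(diff(mean_se) > 0))
})

test_that("template_noise and gaussian_walk kinds produce valid series", {
  tn <- generate_signal(signal_model("template_noise", noise_sd = 0.1,
                                     amplitude = 2, seed = 4), 300)
  expect_length(tn, 300)
  gw <- generate_signal(signal_model("gaussian_walk", noise_sd = 1, seed = 4),
                        300)
  expect_equal(gw, cumsum(diff(c(0, gw))), tolerance = 1e-12)
  expect_error(signal_model("mix", p = 1.5), "p must lie")
})

test_that("generated trials invert the COP relation exactly", {
  d <- cohort_design(seed = 19)
  rec <- generate_trial(d, "A05", "SP", 3)
  truth <- attr(rec, "cop_true")
  cop <- compute_cop(rec)
  expect_lt(max(abs(cop$ap - truth$ap)), 1e-9)
  expect_lt(max(abs(cop$ml - truth$ml)), 1e-9)
  expect_identical(nrow(rec$channels), 1500L)
  expect_identical(rec$meta$group, "biathlete")
  expect_error(generate_trial(d, "Z99", "QS", 1), "unknown subject")
  expect_error(generate_trial(d, "A01", "QS", 7), "repeat_index")
})

test_that("biathletes sway more regularly than controls in the shooting task", {
  wins <- vapply(1:20, function(k) {
    d <- cohort_design(seed = 3000 + k)
    se_b <- sample_entropy(preprocess_trial(
      generate_trial(d, "A01", "SP", 1))$ap)$value
    se_c <- sample_entropy(preprocess_trial(
      generate_trial(d, "C01", "SP", 1))$ap)$value
    se_b < se_c
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("cohort generation covers the full design with a manifest", {
  d <- small_design(seed = 9)
  co <- generate_cohort(d)
  expect_length(co$recordings, 9 * 3 * 2)
  expect_identical(nrow(co$manifest), 54L)
  expect_identical(sort(unique(co$manifest$group)),
                   sort(c("control", "beginner", "biathlete")))
  # names track the manifest
  expect_identical(names(co$recordings)[1],
                   with(co$manifest[1, ],
                        sprintf("%s/%s/%d", subject, task, repeat_index)))
})

test_that("default effect matrices encode the expected qualitative pattern", {
  em <- default_effect_matrix()
  expect_identical(dim(em), c(3L, 3L))
  # QS: near-common irregularity across groups
  expect_lt(diff(range(em[, "QS"])), 0.1)
  # SP/AT: biathletes below both other groups; others above their QS level
  for (t in c("SP", "AT")) {
    expect_lt(em["biathlete", t], min(em[c("control", "beginner"), t]))
    expect_gt(em["control", t], em["control", "QS"])
  }
  expect_true(all(null_effect_matrix(0.5) == 0.5))
  sm <- sampen_effect_means()
  for (t in c("SP", "AT")) {
    expect_lt(sm["biathlete", t], min(sm[c("control", "beginner"), t]))
    expect_lt(sm["biathlete", t], sm["biathlete", "QS"])
  }
})

test_that("simulated SampEn tables honor the design dimensions and seed", {
  tab <- simulate_sampen_trials(seed = 42)
  expect_identical(nrow(tab), 38L * 3L * 3L)
  expect_identical(tab, simulate_sampen_trials(seed = 42))
  expect_false(identical(tab$sampen,
                         simulate_sampen_trials(seed = 43)$sampen))
})
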