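test_that("repeats average arithmetically and missing values are handled", {
  tab <- data.frame(subject = "s1", group = "control", task = "QS",
                    repeat_index = 1:3, direction = "AP",
                    sampen = c(0.9, 1.0, 1.1))
  m <- average_repeats(tab)
  expect_equal(m$sampen, 1.0)
  expect_identical(m$n_repeats, 3L)

  tab$sampen <- c(0.8, Inf, 1.2)
  expect_warning(m2 <- average_repeats(tab), "excluded")
  expect_equal(m2$sampen, 1.0)
  expect_identical(m2$n_repeats, 2L)
})

test_that("a full cohort collapses to 38 x 3 x 2 = 228 condition means", {
  tab <- rbind(simulate_sampen_trials(direction = "AP", seed = 31),
               simulate_sampen_trials(direction = "ML", seed = 32))
  m <- average_repeats(tab)
  expect_identical(nrow(m), 228L)
  expect_true(all(m$n_repeats == 3L))
})

test_that("assumption checks flag per cell and skip degenerate cells", {
  tab <- simulate_sampen_trials(seed = 51)
  m <- average_repeats(tab)
  chk <- check_assumptions(m, "AP")
  expect_identical(nrow(chk$shapiro), 9L)
  expect_identical(nrow(chk$levene), 3L)
  expect_true(chk$mauchly_p >= 0 && chk$mauchly_p <= 1)

  # identical values in one cell: Shapiro-Wilk undefined, skipped loudly
  m2 <- m
  m2$sampen[m2$group == "biathlete" & m2$task == "QS"] <- 1.5
  expect_warning(chk2 <- check_assumptions(m2, "AP"), "skipped")
  expect_true(is.na(
    chk2$shapiro$p[chk2$shapiro$group == "biathlete" &
                   chk2$shapiro$task == "QS"]))
})

test_that("Gaussian cohorts pass assumption flags at roughly the 1 - alpha rate", {
  set.seed(61)
  null_means <- matrix(1.7, 3, 3)
  rates <- replicate(60, {
    tab <- simulate_sampen_trials(means = null_means,
                                  seed = sample.int(1e6, 1))
    chk <- check_assumptions(average_repeats(tab), "AP")
    c(shapiro = mean(chk$shapiro$pass), levene = mean(chk$levene$pass))
  })
  # 9 Shapiro cells and 3 Levene tests per cohort, each nominal alpha=.05
  expect_gt(mean(rates["shapiro", ]), 0.85)
  expect_gt(mean(rates["levene", ]), 0.85)
})

test_that("mixed ANOVA reproduces the design df for 15/15/8 x 3 tasks", {
  tab <- simulate_sampen_trials(seed = 71)
  rep_ap <- mixed_anova(average_repeats(tab), "AP")
  e <- rep_ap$effects
  expect_identical(e$df_num, c(2L, 2L, 4L))
  expect_identical(e$df_den, c(35L, 70L, 70L))
  expect_true(all(e$eta_g_sq >= 0 & e$eta_g_sq <= 1))
})

test_that("mixed ANOVA matches hand-computed sums of squares (balanced)", {
  set.seed(81)
  n_per <- 5
  Y <- matrix(rnorm(2 * n_per * 3, mean = 1.5, sd = 0.3), 2 * n_per, 3)
  rownames(Y) <- sprintf("s%02d", seq_len(2 * n_per))
  colnames(Y) <- c("QS", "SP", "AT")
  group <- factor(rep(c("control", "beginner"), each = n_per),
                  levels = c("control", "beginner"))
  # add structure so no effect is exactly null
  Y[group == "beginner", ] <- Y[group == "beginner", ] + 0.2
  Y[, "SP"] <- Y[, "SP"] + 0.1

  hand <- hand_mixed_anova(Y, group)
  m <- average_repeats(means_to_trials(Y, group))
  fit <- mixed_anova(m, "AP")
  e <- fit$effects
  expect_equal(e$F[e$effect == "group"], hand$F_group, tolerance = 1e-8)
  expect_equal(e$F[e$effect == "task"], hand$F_task, tolerance = 1e-8)
  expect_equal(e$F[e$effect == "group x task"], hand$F_int, tolerance = 1e-8)
  expect_equal(e$eta_g_sq[e$effect == "group"], hand$ges_group,
               tolerance = 1e-8)
  expect_equal(e$eta_g_sq[e$effect == "task"], hand$ges_task,
               tolerance = 1e-8)
  expect_equal(e$eta_g_sq[e$effect == "group x task"], hand$ges_int,
               tolerance = 1e-8)
})

test_that("eta_G^2 is zero for an effect with no between-cell variance", {
  # deterministic table: task effect present, group effect exactly zero
  subj <- sprintf("s%02d", 1:8)
  base <- c(1.1, 1.3, 1.6, 1.2, 1.15, 1.35, 1.55, 1.25)
  Y <- cbind(QS = base, SP = base + 0.4, AT = base + 0.4)
  rownames(Y) <- subj
  # mirror-matched groups: identical group cell means by construction
  group <- factor(rep(c("control", "beginner"), each = 4),
                  levels = c("control", "beginner"))
  Y[5:8, ] <- Y[1:4, ]
  m <- average_repeats(means_to_trials(Y, group))
  # SP and AT columns are identical, so the within-subject covariance is
  # singular and the sphericity test is legitimately skipped (warns)
  e <- suppressWarnings(mixed_anova(m, "AP"))$effects
  expect_equal(e$eta_g_sq[e$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(e$eta_g_sq[e$effect == "group x task"], 0, tolerance = 1e-12)
})

test_that("degenerate zero-variance data raise rather than report", {
  Y <- matrix(1.5, 8, 3, dimnames = list(sprintf("s%d", 1:8),
                                         c("QS", "SP", "AT")))
  group <- factor(rep(c("control", "beginner"), each = 4))
  m <- average_repeats(means_to_trials(Y, group))
  expect_error(suppressWarnings(mixed_anova(m, "AP")), "degenerate|residuals")
})

test_that("post hocs use the Bonferroni product capped at one, per scope", {
  tab <- simulate_sampen_trials(seed = 91)
  m <- average_repeats(tab)
  a <- mixed_anova(m, "AP")
  ph <- pairwise_posthoc(m, a)
  df <- as.data.frame(ph)
  expect_identical(nrow(df), 18L)  # 9 between + 9 within
  for (sc in unique(df$scope)) {
    sel <- df$scope == sc
    expect_identical(sum(sel), 9L)
    expect_equal(df$p_adj[sel], pmin(1, 9 * df$p_raw[sel]), tolerance = 1e-12)
  }
  expect_true(all(df$p_adj >= df$p_raw))
})

test_that("post hocs recover the planted group-by-task separation", {
  # biathlete SP/AT shifted far below the others
  means <- rbind(control = c(1.7, 2.05, 2.05),
                 beginner = c(1.7, 2.05, 2.05),
                 biathlete = c(1.7, 1.10, 1.10))
  colnames(means) <- c("QS", "SP", "AT")
  tab <- simulate_sampen_trials(means = means, seed = 101)
  m <- average_repeats(tab)
  ph <- as.data.frame(pairwise_posthoc(m, mixed_anova(m, "AP")))
  bet <- ph[ph$scope == "between-groups-within-task", ]
  qs <- bet[bet$within == "QS", ]
  expect_false(any(qs$significant))
  for (t in c("SP", "AT")) {
    tt <- bet[bet$within == t, ]
    expect_true(all(tt$significant[grepl("biathlete", tt$pair)]))
    expect_false(tt$significant[tt$pair == "control vs beginner"])
  }
})

test_that("effect sizes classify into the Cohen bands", {
  expect_identical(classify_effect_size(0.272), "large")
  expect_identical(classify_effect_size(0.079), "medium")
  expect_identical(classify_effect_size(0.005), "below_small")
  expect_identical(classify_effect_size(c(0.01, 0.06, 0.14)),
                   c("small", "medium", "large"))
  expect_identical(classify_effect_size(0.0599999), "small")
  expect_error(classify_effect_size(1.2), "\\[0, 1\\]")
  expect_error(classify_effect_size(-0.1), "\\[0, 1\\]")
})
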