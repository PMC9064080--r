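# shared fixtures and independent oracles, all built in code

# constant-channel recording: COP is (my0 = -cop_x * fz0, mx0 = cop_y * fz0)
const_recording <- function(n = 100, fz0 = 700, mx0 = 70, my0 = -35,
                            fs = 50, meta = NULL) {
  force_plate_recording(fx = rep(0, n), fy = rep(0, n), fz = rep(fz0, n),
                        mx = rep(mx0, n), my = rep(my0, n),
                        mz = rep(0, n), fs = fs, meta = meta)
}

rand_recording <- function(n = 120, fs = 50, seed = 1) {
  set.seed(seed)
  force_plate_recording(fx = rnorm(n, 0, 5), fy = rnorm(n, 0, 5),
                        fz = runif(n, 600, 800),
                        mx = rnorm(n, 0, 30), my = rnorm(n, 0, 30),
                        mz = rnorm(n, 0, 2), fs = fs)
}

# analytic magnitude response of an order-`order` analog Butterworth
# low-pass at frequency f (Hz) for cut-off fc (Hz)
butter_gain <- function(f, fc, order = 4) {
  1 / sqrt(1 + (f / fc)^(2 * order))
}

# classical balanced-design mixed-ANOVA sums of squares computed from
# cell and marginal means only (hand formulas); Y is subjects x tasks,
# group a factor with equal group sizes
hand_mixed_anova <- function(Y, group) {
  t_lev <- ncol(Y)
  n <- nrow(Y)
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  g_means <- tapply(subj_means, group, mean)
  task_means <- colMeans(Y)
  ss_group <- t_lev * sum(table(group) * (g_means - grand)^2)
  ss_subj <- t_lev * sum((subj_means - g_means[group])^2)
  ss_task <- n * sum((task_means - grand)^2)
  cell <- matrix(NA_real_, nlevels(group), t_lev)
  for (gi in seq_len(nlevels(group))) {
    cell[gi, ] <- colMeans(Y[group == levels(group)[gi], , drop = FALSE])
  }
  ng <- as.numeric(table(group))
  ss_int <- 0
  for (gi in seq_len(nlevels(group))) {
    for (ti in seq_len(t_lev)) {
      ss_int <- ss_int + ng[gi] *
        (cell[gi, ti] - g_means[gi] - task_means[ti] + grand)^2
    }
  }
  resid <- Y
  for (i in seq_len(n)) {
    gi <- as.integer(group[i])
    resid[i, ] <- Y[i, ] - subj_means[i] - cell[gi, ] + g_means[gi]
  }
  ss_err_w <- sum(resid^2)
  df_g <- nlevels(group) - 1
  df_s <- n - nlevels(group)
  df_t <- t_lev - 1
  df_i <- df_g * df_t
  df_ew <- df_s * df_t
  lapply(list(
    F_group = (ss_group / df_g) / (ss_subj / df_s),
    F_task = (ss_task / df_t) / (ss_err_w / df_ew),
    F_int = (ss_int / df_i) / (ss_err_w / df_ew),
    ges_group = ss_group / (ss_group + ss_subj + ss_err_w),
    ges_task = ss_task / (ss_task + ss_subj + ss_err_w),
    ges_int = ss_int / (ss_int + ss_subj + ss_err_w)
  ), unname)
}

# long trial table from a subjects x tasks matrix of per-subject means
# (one repeat), for feeding average_repeats / mixed_anova directly
means_to_trials <- function(Y, group, direction = "AP") {
  rows <- list()
  for (i in seq_len(nrow(Y))) {
    for (t in colnames(Y)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = rownames(Y)[i], group = as.character(group[i]), task = t,
        repeat_index = 1L, direction = direction, sampen = Y[i, t])
    }
  }
  do.call(rbind, rows)
}

small_design <- function(seed = 1) {
  cohort_design(group_sizes = c(control = 3L, beginner = 3L, biathlete = 3L),
                repeats = 2L, seed = seed)
}
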