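.groups <- c("control", "beginner", "biathlete")
.tasks <- c("QS", "SP", "AT")

.validate_trials <- function(trials) {
  need <- c("subject", "group", "task", "repeat_index", "direction", "sampen")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop(sprintf("trial table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  trials$group <- factor(as.character(trials$group), levels = .groups)
  trials$task <- factor(as.character(trials$task), levels = .tasks)
  trials$direction <- factor(as.character(trials$direction),
                             levels = c("AP", "ML"))
  if (anyNA(trials$group) || anyNA(trials$task) || anyNA(trials$direction)) {
    stop("group, task and direction must use the canonical level names",
         call. = FALSE)
  }
  trials
}

#' Average repeated measurements per subject and condition
#'
#' Collapses the three repeats of each (subject, task, direction) cell to
#' their arithmetic mean, the per-subject dependent variable entering the
#' ANOVA. Non-finite SampEn values (the `+Inf` sentinel for series with
#' no length-(m+1) matches, or `NA`) are excluded with a warning; a cell
#' with no usable repeat at all is an error.
#'
#' @param trials Long-format data frame with columns `subject`, `group`,
#'   `task`, `repeat_index`, `direction`, `sampen`.
#' @return Data frame with one row per (subject, task, direction):
#'   columns `subject`, `group`, `task`, `direction`, `sampen`,
#'   `n_repeats`.
#' @export
average_repeats <- function(trials) {
  trials <- .validate_trials(trials)
  bad <- !is.finite(trials$sampen)
  if (any(bad)) {
    warning(sprintf(
      "%d trial(s) with missing or infinite SampEn excluded from averaging",
      sum(bad)), call. = FALSE)
    trials <- trials[!bad, , drop = FALSE]
  }
  key <- interaction(trials$subject, trials$task, trials$direction,
                     drop = TRUE)
  pieces <- split(trials, key)
  out <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(subject = d$subject[1], group = d$group[1], task = d$task[1],
               direction = d$direction[1], sampen = mean(d$sampen),
               n_repeats = nrow(d))
  }))
  rownames(out) <- NULL
  # every subject x task x direction combination present in the input
  # metadata must survive with at least one repeat
  out[order(out$direction, out$group, out$subject, out$task), ]
}

# subjects x tasks response matrix for one direction, plus group vector
.wide_response <- function(means, direction) {
  d <- means[means$direction == direction, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no data for direction %s", direction),
                     call. = FALSE)
  subjects <- unique(d$subject)
  Y <- matrix(NA_real_, length(subjects), length(.tasks),
              dimnames = list(subjects, .tasks))
  for (i in seq_len(nrow(d))) {
    Y[as.character(d$subject[i]), as.character(d$task[i])] <- d$sampen[i]
  }
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    stop(sprintf("missing cell: subject %s, task %s",
                 rownames(Y)[miss[1, 1]], colnames(Y)[miss[1, 2]]),
         call. = FALSE)
  }
  grp <- d$group[match(subjects, d$subject)]
  list(Y = Y, group = factor(as.character(grp), levels = .groups),
       subjects = subjects)
}

#' Check distributional assumptions for the mixed ANOVA
#'
#' Shapiro-Wilk normality per group-by-task cell, classical Levene's test
#' (centered on the mean) for homogeneity of variance across groups
#' within each task, and Mauchly's sphericity test for the within-subject
#' task factor. Results are flags at the given alpha, not hard failures;
#' cells too small or degenerate for a test are skipped with a warning.
#'
#' @param means Output of [average_repeats()].
#' @param direction `"AP"` or `"ML"`.
#' @param alpha Significance level for flagging (default 0.05).
#' @return A list with `shapiro` (data frame per cell), `levene` (data
#'   frame per task), `mauchly_w`, `mauchly_p`, and `alpha`.
#' @export
check_assumptions <- function(means, direction = c("AP", "ML"),
                              alpha = 0.05) {
  direction <- match.arg(direction)
  w <- .wide_response(means, direction)
  grp <- droplevels(w$group)
  sh <- do.call(rbind, lapply(levels(grp), function(g) {
    do.call(rbind, lapply(.tasks, function(t) {
      v <- w$Y[grp == g, t]
      if (length(v) < 3L || .pop_sd(v) == 0) {
        warning(sprintf(
          "Shapiro-Wilk skipped for cell %s/%s (n = %d, degenerate or too small)",
          g, t, length(v)), call. = FALSE)
        return(data.frame(group = g, task = t, n = length(v),
                          W = NA_real_, p = NA_real_, pass = NA))
      }
      st <- stats::shapiro.test(v)
      data.frame(group = g, task = t, n = length(v),
                 W = unname(st$statistic), p = st$p.value,
                 pass = st$p.value > alpha)
    }))
  }))
  lv <- do.call(rbind, lapply(.tasks, function(t) {
    lt <- car::leveneTest(w$Y[, t] ~ grp, center = mean)
    data.frame(task = t, F = lt[1, "F value"], p = lt[1, "Pr(>F)"],
               pass = lt[1, "Pr(>F)"] > alpha)
  }))
  if (length(.tasks) <= 2L) {
    # sphericity is automatic with two within-subject levels
    mw <- 1; mp <- 1
  } else {
    fit <- .mlm_fit(w)
    s <- .anova_summary(fit)
    sph <- s$sphericity.tests
    if (is.null(sph) || !"task" %in% rownames(sph)) {
      # singular within-subject covariance (e.g. duplicated task columns)
      warning("Mauchly test skipped: within-subject covariance is singular",
              call. = FALSE)
      mw <- NA_real_; mp <- NA_real_
    } else {
      mw <- sph["task", "Test statistic"]
      mp <- sph["task", "p-value"]
    }
  }
  list(shapiro = sh, levene = lv, mauchly_w = unname(mw),
       mauchly_p = unname(mp), alpha = alpha)
}

.mlm_fit <- function(w) {
  dat <- data.frame(group = droplevels(w$group))
  model <- stats::lm(w$Y ~ group, data = dat,
                     contrasts = list(group = "contr.sum"))
  list(model = model, idata = data.frame(task = factor(.tasks,
                                                       levels = .tasks)))
}

# univariate mixed-design summary; muffles the cosmetic "HF eps > 1" note
.anova_summary <- function(fit) {
  withCallingHandlers(
    summary(car::Anova(fit$model, idata = fit$idata, idesign = ~task,
                       type = 3), multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
}

#' Two-way mixed-design ANOVA on subject-condition means
#'
#' Fits the standard univariate mixed-design ANOVA with group as the
#' between-subjects factor and task as the within-subjects factor, using
#' type-III sums of squares (sum-to-zero contrasts), which handles the
#' unbalanced group sizes. For each effect it reports F, numerator and
#' denominator df, p, and the generalized eta squared
#' `eta_G^2 = SS_effect / (SS_effect + SS_subjects + SS_task_x_subjects)`
#' (Bakeman's formulation, with all subject-related variance in the
#' denominator). When Mauchly's test rejects sphericity at `alpha`, a
#' Greenhouse-Geisser corrected p-value is reported alongside the
#' uncorrected one (the uncorrected F/df remain primary).
#'
#' @param means Output of [average_repeats()].
#' @param direction `"AP"` or `"ML"`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `anova_report`: a list with `direction`,
#'   `effects` (data frame: effect, F, df_num, df_den, p, p_gg, eta_g_sq,
#'   magnitude), `assumptions`, and `alpha`.
#' @export
mixed_anova <- function(means, direction = c("AP", "ML"), alpha = 0.05) {
  direction <- match.arg(direction)
  w <- .wide_response(means, direction)
  if (nlevels(droplevels(w$group)) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  fit <- .mlm_fit(w)
  s <- .anova_summary(fit)
  uni <- s$univariate.tests
  eff_rows <- c(group = "group", task = "task", `group:task` = "group:task")
  ss_err_between <- uni["group", "Error SS"]
  ss_err_within <- uni["task", "Error SS"]
  if (ss_err_between <= 0 || ss_err_within <= 0) {
    stop("degenerate data: zero residual variance", call. = FALSE)
  }
  denom_err <- ss_err_between + ss_err_within
  adj <- s$pval.adjustments
  effects <- do.call(rbind, lapply(names(eff_rows), function(nm) {
    row <- uni[eff_rows[[nm]], ]
    ges <- row[["Sum Sq"]] / (row[["Sum Sq"]] + denom_err)
    p_gg <- NA_real_
    if (!is.null(adj) && eff_rows[[nm]] %in% rownames(adj)) {
      p_gg <- adj[eff_rows[[nm]], "Pr(>F[GG])"]
    }
    data.frame(effect = sub(":", " x ", nm),
               F = row[["F value"]],
               df_num = as.integer(row[["num Df"]]),
               df_den = as.integer(row[["den Df"]]),
               p = row[["Pr(>F)"]],
               p_gg = p_gg,
               eta_g_sq = ges,
               magnitude = classify_effect_size(ges))
  }))
  rownames(effects) <- NULL
  assumptions <- check_assumptions(means, direction, alpha)
  if (!is.na(assumptions$mauchly_p) && assumptions$mauchly_p >= alpha) {
    effects$p_gg <- NA_real_  # correction reported only when sphericity fails
  }
  structure(list(direction = direction, effects = effects,
                 assumptions = assumptions, alpha = alpha,
                 ss_err_between = unname(ss_err_between),
                 ss_err_within = unname(ss_err_within)),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA (%s direction), alpha = %g\n",
              x$direction, x$alpha))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-12s F = %.3f; df = %d, %d; p %s; eta_G^2 = %.3f (%s)%s\n",
                e$effect[i], e$F[i], e$df_num[i], e$df_den[i],
                if (e$p[i] < 0.001) "< 0.001" else sprintf("= %.3f", e$p[i]),
                e$eta_g_sq[i], e$magnitude[i],
                if (!is.na(e$p_gg[i]))
                  sprintf(" [GG p = %.3f]", e$p_gg[i]) else ""))
  }
  cat(sprintf("  Mauchly W = %.3f, p = %.3f\n",
              x$assumptions$mauchly_w, x$assumptions$mauchly_p))
  invisible(x)
}

#' Bonferroni-corrected pairwise post-hoc t-tests
#'
#' Runs the two post-hoc families following a significant omnibus effect:
#' between-group comparisons within each task (Welch two-sample t-tests)
#' and between-task comparisons within each group (paired t-tests). Each
#' scope is its own Bonferroni family: `p_adj = min(1, k * p_raw)` with k
#' the number of comparisons in that scope (9 each under the full
#' 3-group, 3-task design). By default comparisons are computed only for
#' scopes licensed by a significant omnibus effect (group or interaction
#' for the between scope; task or interaction for the within scope);
#' `force = TRUE` computes both regardless.
#'
#' @param means Output of [average_repeats()].
#' @param anova An `anova_report` from [mixed_anova()] for the same
#'   direction.
#' @param alpha Significance level (default 0.05).
#' @param force Compute both families even without a significant omnibus
#'   effect.
#' @return An object of class `pairwise_report`: data frame with columns
#'   `direction`, `scope`, `within`, `pair`, `t`, `df`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
pairwise_posthoc <- function(means, anova, alpha = 0.05, force = FALSE) {
  stopifnot(inherits(anova, "anova_report"))
  w <- .wide_response(means, anova$direction)
  e <- anova$effects
  p_of <- function(nm) e$p[e$effect == nm]
  do_between <- force || p_of("group") < alpha || p_of("group x task") < alpha
  do_within <- force || p_of("task") < alpha || p_of("group x task") < alpha
  rows <- list()
  if (do_between) {
    pairs <- utils::combn(.groups, 2, simplify = FALSE)
    for (t in .tasks) {
      for (pr in pairs) {
        v1 <- w$Y[w$group == pr[1], t]
        v2 <- w$Y[w$group == pr[2], t]
        if (length(v1) < 2L || length(v2) < 2L) {
          warning(sprintf("comparison %s vs %s in %s skipped (n < 2)",
                          pr[1], pr[2], t), call. = FALSE)
          next
        }
        tt <- stats::t.test(v1, v2)
        rows[[length(rows) + 1L]] <- data.frame(
          direction = anova$direction, scope = "between-groups-within-task",
          within = t, pair = paste(pr, collapse = " vs "),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p_raw = tt$p.value)
      }
    }
  }
  if (do_within) {
    pairs <- utils::combn(.tasks, 2, simplify = FALSE)
    for (g in .groups) {
      for (pr in pairs) {
        sel <- w$group == g
        if (sum(sel) < 2L) {
          warning(sprintf("comparison %s vs %s in group %s skipped (n < 2)",
                          pr[1], pr[2], g), call. = FALSE)
          next
        }
        tt <- stats::t.test(w$Y[sel, pr[1]], w$Y[sel, pr[2]], paired = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          direction = anova$direction, scope = "between-tasks-within-group",
          within = g, pair = paste(pr, collapse = " vs "),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p_raw = tt$p.value)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), scope = character(),
               within = character(), pair = character(), t = numeric(),
               df = numeric(), p_raw = numeric())
  if (nrow(out)) {
    out$p_adj <- NA_real_
    for (sc in unique(out$scope)) {
      k <- sum(out$scope == sc)
      out$p_adj[out$scope == sc] <- pmin(1, k * out$p_raw[out$scope == sc])
    }
    out$significant <- out$p_adj < alpha
  }
  rownames(out) <- NULL
  structure(out, class = c("pairwise_report", "data.frame"))
}

#' Classify a generalized eta squared value
#'
#' Cohen's bands for effect size: below 0.01 is below-small, 0.01 to 0.06
#' small, 0.06 to 0.14 medium, and 0.14 or more large.
#'
#' @param eta_g_sq Numeric vector of values in \[0, 1\].
#' @return Character vector: `"below_small"`, `"small"`, `"medium"` or
#'   `"large"`.
#' @export
classify_effect_size <- function(eta_g_sq) {
  if (any(!is.finite(eta_g_sq)) || any(eta_g_sq < 0) || any(eta_g_sq > 1)) {
    stop("eta_g_sq must lie in [0, 1]", call. = FALSE)
  }
  cut_labels <- c("below_small", "small", "medium", "large")
  as.character(cut(eta_g_sq, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf),
                   labels = cut_labels, right = FALSE))
}
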