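# Independent brute-force oracles used to cross-check the implementation.

# Rates by explicit looping and counting (no vectorized shortcuts).
oracle_rates <- function(ratings, truth, theta) {
  hits <- 0; n <- 0; fas <- 0; m <- 0
  for (i in seq_along(ratings)) {
    if (truth[i] == "same") {
      n <- n + 1
      if (ratings[i] > theta) hits <- hits + 1
    } else {
      m <- m + 1
      if (ratings[i] > theta) fas <- fas + 1
    }
  }
  list(tpr = hits / n, fpr = fas / m,
       acc = (hits + (m - fas)) / (n + m), n = n, m = m)
}

# Exhaustive two-sample permutation p-value for the rank-sum test, built on
# the Mann-Whitney win count rather than ranks (ties count one half).
oracle_ranksum_p <- function(a, b) {
  u_stat <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) {
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    }
    u
  }
  pooled <- c(a, b)
  n1 <- length(a)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  u_obs <- u_stat(a, b)
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Direct sums-of-squares one-way F.
oracle_oneway_F <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  (ss_b / df1) / (ss_w / df2)
}

# Direct SS decomposition for the balanced split-plot layout: subjects in
# groups (between), each observed at both levels of a two-level within
# factor. Returns F for the between and within main effects.
oracle_mixed_F <- function(df) {
  # df: subject, group, within, value; balanced
  gm <- mean(df$value)
  subj_means <- tapply(df$value, df$subject, mean)
  subj_group <- tapply(df$group, df$subject, function(g) g[1])
  grp_means <- tapply(df$value, df$group, mean)
  win_means <- tapply(df$value, df$within, mean)
  a <- length(unique(df$group))
  w <- 2
  s_per_g <- table(subj_group)

  ss_group <- sum(tapply(df$value, df$group,
                         function(v) length(v) * (mean(v) - gm)^2))
  ss_subj_within_g <- sum(w * (subj_means - grp_means[subj_group])^2)
  ss_within <- sum(tapply(df$value, df$within,
                          function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(df$value, list(df$group, df$within), mean)
  ss_gw <- 0
  for (g in rownames(cell_means)) for (l in colnames(cell_means)) {
    ss_gw <- ss_gw + s_per_g[[g]] *
      (cell_means[g, l] - grp_means[[g]] - win_means[[l]] + gm)^2
  }
  ss_tot <- sum((df$value - gm)^2)
  ss_err_within <- ss_tot - ss_group - ss_subj_within_g - ss_within - ss_gw

  n_subj <- length(subj_means)
  df_group <- a - 1
  df_sub_err <- n_subj - a
  df_win <- w - 1
  df_win_err <- (n_subj - a) * (w - 1)
  list(
    F_between = (ss_group / df_group) / (ss_subj_within_g / df_sub_err),
    F_within = (ss_within / df_win) / (ss_err_within / df_win_err),
    F_interaction = (ss_gw / (df_group * df_win)) /
      (ss_err_within / df_win_err),
    ss = c(group = ss_group, subj = ss_subj_within_g, within = ss_within,
           gw = ss_gw, err = ss_err_within, total = ss_tot)
  )
}
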