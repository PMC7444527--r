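test_that("bootstrap intervals are deterministic under a fixed seed", {
  records <- simulate_survey(simulate_raters(sim_config(
    n_volunteers_per_variant = 10, seed = 9)))
  kept <- screen_catch_trials(records)$kept
  stat <- function(r) mean(r$rating)
  cfg <- bootstrap_config(B = 300, seed = 17)
  a <- bootstrap_statistic(kept, stat, cfg)
  b <- bootstrap_statistic(kept, stat, cfg)
  expect_identical(a, b)
  c_ <- bootstrap_statistic(kept, stat, bootstrap_config(B = 300, seed = 18))
  expect_false(identical(a$lower, c_$lower))
})

test_that("identical volunteers give a zero-width interval", {
  one <- control_volunteer("X", c(2, 1, 0), c(-1, -2, 0))[1:6, ]
  clones <- dplyr::bind_rows(lapply(1:5, function(i) {
    out <- one
    out$volunteer_id <- paste0("X", i)
    out
  }))
  res <- bootstrap_statistic(clones, function(r) mean(r$rating),
                             bootstrap_config(B = 100, seed = 1))
  expect_equal(res$lower, res$estimate)
  expect_equal(res$upper, res$estimate)
})

test_that("percentile interval contains the plug-in estimate for a mean", {
  set.seed(99)
  for (rep in 1:5) {
    recs <- simulate_survey(simulate_raters(sim_config(
      n_volunteers_per_variant = 8, seed = 100 + rep)))
    kept <- screen_catch_trials(recs)$kept
    res <- bootstrap_statistic(kept, function(r) mean(r$rating),
                               bootstrap_config(B = 200, seed = rep))
    expect_lte(res$lower, res$estimate)
    expect_gte(res$upper, res$estimate)
  }
})

test_that("bootstrap refuses degenerate statistics", {
  records <- dplyr::bind_rows(
    control_volunteer("A", c(3, 3), c(-3, -3)),
    control_volunteer("B", c(3, 3), c(-3, -3))
  )
  kept <- screen_catch_trials(records)$kept
  # d' is undefined on the pooled sample itself (rates saturate at 0/1)
  stat <- function(r) {
    p <- rates_at_threshold(r, 0.5)
    dprime_criterion(p$tpr, p$fpr)$dprime
  }
  expect_error(
    bootstrap_statistic(kept, stat, bootstrap_config(B = 50, seed = 2)),
    "full sample")

  # a statistic defined on the full sample but failing on most resamples
  # (all three volunteers appear together in only 6/27 resamples)
  three <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(id) {
    control_volunteer(id, c(3, 1), c(-3, -1))
  }))
  kept3 <- screen_catch_trials(three)$kept
  fragile <- function(r) {
    if (length(unique(r$volunteer_id)) < 3) NA_real_ else mean(r$rating)
  }
  expect_error(
    bootstrap_statistic(kept3, fragile, bootstrap_config(B = 200, seed = 3)),
    "replicates")

  expect_error(
    bootstrap_statistic(kept[0, ], function(r) 1, bootstrap_config()),
    "2 distinct volunteers")
})

test_that("rank-sum test matches textbook exact cases", {
  same <- rank_sum_item_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- rank_sum_item_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1)  # 2 * 1/20 exact

  const <- rank_sum_item_test(c(2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)

  expect_error(rank_sum_item_test(numeric(0), c(1)), "non-empty")
})

test_that("exact rank-sum p equals the exhaustive permutation oracle", {
  set.seed(31)
  for (rep in 1:12) {
    a <- sample(-3:3, sample(3:6, 1), replace = TRUE)
    b <- sample(-3:3, sample(3:6, 1), replace = TRUE)
    res <- rank_sum_item_test(a, b)
    expect_equal(res$p_value, oracle_ranksum_p(a, b),
                 info = paste("a:", paste(a, collapse = ","),
                              "b:", paste(b, collapse = ",")))
  }
})

test_that("large-sample rank-sum uses the tie-corrected normal approximation", {
  set.seed(77)
  a <- sample(-3:3, 40, replace = TRUE)
  b <- sample(-2:3, 45, replace = TRUE)
  res <- rank_sum_item_test(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, correct = FALSE, exact = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(res$method, "tie-corrected")
})

test_that("paired variant defers to the signed-rank test", {
  set.seed(5)
  x <- sample(-3:3, 12, replace = TRUE)
  y <- pmin(3, x + sample(0:2, 12, replace = TRUE))
  res <- rank_sum_item_test(x, y, paired = TRUE)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  expect_equal(res$p_value, ref$p.value)
})

test_that("item shift summary handles typical and degenerate inputs", {
  zero <- item_shift_summary(c(1, 2, 1.5), c(1, 2, 1.5))
  expect_equal(zero$mean_shift, 0)
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)

  deg <- item_shift_summary(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$mean_shift, 1)
  expect_identical(deg$statistic, Inf)
  expect_equal(deg$p_value, 0)

  set.seed(8)
  d <- rnorm(12, 0.4, 0.4)
  res <- item_shift_summary(d, rep(0, 12))
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)
  expect_equal(res$df, 11)
  expect_error(item_shift_summary(1, 2), "2 items")
})

test_that("chi-squared reproduces the demographic blocking statistics", {
  gender <- matrix(c(50, 62, 63, 53, 57, 57), nrow = 2, byrow = TRUE)
  res_g <- chi_squared_test(gender)
  expect_equal(res_g$statistic, 0.41, tolerance = 0.005)
  expect_identical(res_g$df, 2L)

  race <- matrix(c(50, 47, 61, 32, 48, 47, 21, 24, 12), nrow = 3, byrow = TRUE)
  res_r <- chi_squared_test(race)
  expect_equal(res_r$statistic, 8.25, tolerance = 0.005)
  expect_identical(res_r$df, 4L)
})

test_that("chi-squared invariances: proportional rows, permutation, scaling", {
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(chi_squared_test(prop)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_squared_test(prop)$p_value, 1)

  tab <- matrix(c(12, 7, 4, 9, 3, 11), nrow = 2)
  base <- chi_squared_test(tab)$statistic
  expect_equal(chi_squared_test(tab[, c(3, 1, 2)])$statistic, base)
  expect_equal(chi_squared_test(tab[c(2, 1), ])$statistic, base)
  expect_equal(chi_squared_test(3 * tab)$statistic, 3 * base)

  expect_error(chi_squared_test(rbind(c(0, 0), c(1, 2))), "row")
  expect_error(chi_squared_test(cbind(c(0, 0), c(1, 2))), "column")
})

test_that("one-way ANOVA agrees with the direct sums-of-squares oracle", {
  set.seed(12)
  for (rep in 1:8) {
    groups <- lapply(1:3, function(i) rnorm(sample(4:9, 1), mean = i / 4))
    res <- oneway_anova(groups)
    expect_equal(res$statistic, oracle_oneway_F(groups), tolerance = 1e-12)
  }

  ident <- oneway_anova(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # two-group F equals the squared pooled t statistic
  a <- rnorm(10)
  b <- rnorm(12, 0.5)
  res2 <- oneway_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(oneway_anova(list(1, c(1, 2))), "at least 2")
})

test_that("mixed ANOVA matches the brute-force SS decomposition", {
  set.seed(21)
  n_per_group <- c(6, 8)
  subj <- sprintf("S%02d", seq_len(sum(n_per_group)))
  grp <- rep(c("g1", "g2"), n_per_group)
  df <- expand.grid(subject = subj, within = c("told_same", "told_diff"),
                    stringsAsFactors = FALSE)
  df$group <- grp[match(df$subject, subj)]
  df$value <- rnorm(nrow(df)) + 0.3 * (df$within == "told_diff") +
    0.2 * (df$group == "g2") + rnorm(length(subj))[match(df$subject, subj)]

  res <- mixed_anova(df[c("subject", "within", "value")],
                     between = setNames(grp, subj))
  o <- oracle_mixed_F(df)
  expect_equal(res$statistic[res$term == "group"], o$F_between,
               tolerance = 1e-10)
  expect_equal(res$statistic[res$term == "within"], o$F_within,
               tolerance = 1e-10)
  expect_equal(res$statistic[res$term == "group:within"], o$F_interaction,
               tolerance = 1e-10)
  # decomposition is exhaustive
  expect_equal(sum(o$ss[1:5]), o$ss[["total"]], tolerance = 1e-9)
})

test_that("mixed ANOVA degrees of freedom follow the pooled layout", {
  set.seed(22)
  n <- 30
  df <- data.frame(subject = rep(sprintf("S%02d", 1:n), each = 2),
                   within = rep(c("same", "different"), n),
                   value = rnorm(2 * n))
  res <- mixed_anova(df)
  expect_equal(res$df2, n - 1)

  flat <- df
  flat$value <- rep(rnorm(n), each = 2)  # no within-subject difference
  res0 <- mixed_anova(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(mixed_anova(df[-1, ]), "S01")
})

test_that("within-subject effect of realistic size is detected reliably", {
  set.seed(23)
  n <- 200
  delta <- 0.06  # effect on the rate scale
  rejections <- replicate(60, {
    base <- rnorm(n, 0.2, 0.05)
    r_same <- pmin(1, pmax(0, base + delta / 2 +
                             (rbinom(n, 6, 0.2) / 6 - 0.2) / 2))
    r_diff <- pmin(1, pmax(0, base - delta / 2 +
                             (rbinom(n, 6, 0.2) / 6 - 0.2) / 2))
    df <- data.frame(subject = rep(seq_len(n), each = 2),
                     within = rep(c("same", "different"), n),
                     value = as.vector(rbind(r_same, r_diff)))
    mixed_anova(df)$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.8)
})
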