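#' Bootstrap configuration
#'
#' Volunteer-level percentile bootstrap settings. Resampling volunteers with
#' replacement (all of a volunteer's responses move together) respects the
#' clustered structure of the survey; percentile intervals at the 95% level
#' are the default.
#'
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; identical seeds give bit-identical intervals.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 2000, seed = 1L, level = 0.95) {
  stopifnot(B >= 1, level > 0, level < 1)
  structure(list(B = as.integer(B), seed = as.integer(seed), level = level),
            class = "bootstrap_config")
}

#' Bootstrap a statistic over volunteers
#'
#' Resamples volunteers with replacement, optionally within strata (e.g.
#' survey variant), recomputes `statistic` on each resampled response table,
#' and returns the plug-in estimate with a percentile confidence interval.
#' Replicates on which the statistic is undefined (`NA`/`NaN`, or an error)
#' are dropped; if more than half fail, the interval is refused.
#'
#' @param records A validated response tibble with >= 2 distinct volunteers.
#' @param statistic A function `records -> scalar`.
#' @param config A [bootstrap_config()].
#' @param stratify_by Optional column name; volunteers are resampled within
#'   each stratum so stratum sizes are preserved.
#' @return A list: `estimate`, `lower`, `upper`, `level`, `B`, `n_failed`.
#' @export
bootstrap_statistic <- function(records, statistic, config = bootstrap_config(),
                                stratify_by = NULL) {
  stopifnot(inherits(config, "bootstrap_config"), is.function(statistic))
  ids <- unique(records$volunteer_id)
  if (length(ids) < 2) {
    stop("bootstrap needs at least 2 distinct volunteers", call. = FALSE)
  }
  estimate <- tryCatch(statistic(records), error = function(e) NA_real_)
  if (length(estimate) != 1 || !is.finite(estimate)) {
    stop("statistic is undefined on the full sample", call. = FALSE)
  }

  # row indices per volunteer, grouped into strata
  idx_by_vol <- split(seq_len(nrow(records)), records$volunteer_id)
  if (is.null(stratify_by)) {
    strata <- list(ids)
  } else {
    vol_stratum <- records[[stratify_by]][!duplicated(records$volunteer_id)]
    names(vol_stratum) <- records$volunteer_id[!duplicated(records$volunteer_id)]
    strata <- split(names(vol_stratum), vol_stratum)
  }

  set.seed(config$seed)
  reps <- vapply(seq_len(config$B), function(b) {
    take <- unlist(lapply(strata, function(s) {
      s[sample.int(length(s), length(s), replace = TRUE)]
    }), use.names = FALSE)
    rows <- unlist(idx_by_vol[take], use.names = FALSE)
    val <- tryCatch(statistic(records[rows, , drop = FALSE]),
                    error = function(e) NA_real_)
    if (length(val) != 1 || !is.finite(val)) NA_real_ else as.numeric(val)
  }, numeric(1))

  n_failed <- sum(is.na(reps))
  if (n_failed > config$B / 2) {
    stop(sprintf(
      "statistic undefined on %.0f%% of bootstrap replicates; cannot form interval",
      100 * n_failed / config$B), call. = FALSE)
  }
  alpha <- (1 - config$level) / 2
  ci <- quantile(reps[!is.na(reps)], c(alpha, 1 - alpha), names = FALSE,
                 type = 7)
  list(estimate = estimate, lower = ci[1], upper = ci[2],
       level = config$level, B = config$B, n_failed = n_failed)
}

#' Two-sample rank test for per-item response distributions
#'
#' Compares the rating distributions of one face pair under the "same" and
#' "different" prior labels (independent volunteer groups, via the version
#' counterbalancing). Uses the Mann-Whitney form with average ranks for
#' ties. When both groups have at most `exact_max` observations the
#' two-sided p-value is computed by exhaustive enumeration of all group
#' assignments (valid under ties); otherwise the normal approximation with
#' the tie-corrected variance is used, without continuity correction.
#'
#' For genuinely paired observations use `paired = TRUE`, which defers to
#' the Wilcoxon signed-rank test.
#'
#' @param ratings_a,ratings_b Numeric rating vectors (non-empty).
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @param paired Treat the vectors as paired (signed-rank test)?
#' @return A tibble: `statistic` (rank-sum W of group a), `p_value`,
#'   `method`, `shift` (difference in group means).
#' @export
rank_sum_item_test <- function(ratings_a, ratings_b, exact_max = 8,
                               paired = FALSE) {
  if (length(ratings_a) == 0 || length(ratings_b) == 0) {
    stop("both rating groups must be non-empty", call. = FALSE)
  }
  if (paired) {
    ht <- suppressWarnings(wilcox.test(ratings_a, ratings_b, paired = TRUE))
    return(tibble::tibble(statistic = unname(ht$statistic),
                          p_value = ht$p.value,
                          method = "Wilcoxon signed-rank",
                          shift = mean(ratings_a) - mean(ratings_b)))
  }
  n1 <- length(ratings_a)
  n2 <- length(ratings_b)
  pooled <- c(ratings_a, ratings_b)
  r <- rank(pooled)  # average ranks under ties
  w <- sum(r[seq_len(n1)])

  if (length(unique(pooled)) == 1) {
    p <- 1
    method <- "rank-sum (degenerate: all values equal)"
  } else if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    # two-sided exact p: doubled smaller tail, capped at 1
    p_lo <- mean(ws <= w + 1e-9)
    p_hi <- mean(ws >= w - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "rank-sum (exact enumeration)"
  } else {
    mu <- n1 * (n1 + n2 + 1) / 2
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "rank-sum (normal approximation, tie-corrected)"
  }
  tibble::tibble(statistic = w, p_value = p, method = method,
                 shift = mean(ratings_a) - mean(ratings_b))
}

#' Across-item mean shift of per-item label effects
#'
#' Takes the per-item mean rating under the "same" label and under the
#' "different" label, forms the per-item difference, and tests the average
#' shift against zero with a one-sample two-sided t-test on `items - 1`
#' degrees of freedom. A positive shift means labels pulled certainty toward
#' "same". Zero variance of the differences is reported as degenerate: an
#' infinite statistic with p = 0 when the mean shift is non-zero, and a zero
#' statistic with p = 1 when every difference is exactly 0.
#'
#' @param mean_same,mean_diff Per-item mean ratings (equal length >= 2).
#' @return A tibble: `mean_shift`, `statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
item_shift_summary <- function(mean_same, mean_diff) {
  stopifnot(length(mean_same) == length(mean_diff))
  if (length(mean_same) < 2) {
    stop("need at least 2 items", call. = FALSE)
  }
  d <- mean_same - mean_diff
  k <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(mean_shift = 0, statistic = 0, df = k - 1,
                            p_value = 1, degenerate = TRUE))
    }
    return(tibble::tibble(mean_shift = mean(d),
                          statistic = sign(mean(d)) * Inf, df = k - 1,
                          p_value = 0, degenerate = TRUE))
  }
  ht <- t.test(d, mu = 0)
  tibble::tibble(mean_shift = mean(d), statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 degenerate = FALSE)
}

#' Pearson chi-squared test on a contingency table
#'
#' The homogeneity test used for demographic blocking and trust-response
#' comparisons: Pearson's statistic with expected counts from the margins,
#' `(r - 1)(c - 1)` degrees of freedom, and no continuity correction.
#'
#' @param counts A numeric matrix of non-negative counts; every row and
#'   column must have a positive total.
#' @return A tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chi_squared_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0)) {
    stop("zero row margin in row(s) ", paste(which(rs == 0), collapse = ", "),
         call. = FALSE)
  }
  if (any(cs == 0)) {
    stop("zero column margin in column(s) ",
         paste(which(cs == 0), collapse = ", "), call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 method = "Pearson chi-squared (no continuity correction)")
}

#' One-way analysis of variance across groups
#'
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom, via
#' `stats::aov`. When both between- and within-group sums of squares are
#' zero (all values identical), F is defined as 0 with p = 1.
#'
#' @param groups A list (optionally named) of numeric vectors, each of
#'   length >= 2.
#' @return A tibble: `statistic`, `df1`, `df2`, `p_value`, `method`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (sd(y) == 0) {  # no variation anywhere: F defined as 0
    return(tibble::tibble(statistic = 0, df1 = length(groups) - 1,
                          df2 = length(y) - length(groups), p_value = 1,
                          method = "one-way ANOVA"))
  }
  tab <- stats::anova(aov(y ~ g))
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(f)) {
    f <- 0
    p <- 1
  }
  tibble::tibble(statistic = f, df1 = tab$Df[1], df2 = tab$Df[2],
                 p_value = p, method = "one-way ANOVA")
}

#' Repeated-measures ANOVA with a two-level within-subject factor
#'
#' Balanced design: every subject is observed once at each level of the
#' within factor (told-same vs told-different). Returns the F test for the
#' within-subject main effect against the within x subject error stratum,
#' and, when `between` is supplied, the between-subjects main effect tested
#' against subjects-within-groups and the between x within interaction.
#' Without a between factor the within test has `(1, n_subjects - 1)`
#' degrees of freedom.
#'
#' @param values A long tibble/data.frame with columns `subject`, `within`
#'   (exactly 2 levels), and `value`.
#' @param between Optional vector of group labels, one per subject (named by
#'   subject id, or in the order of unique subjects).
#' @return A tibble with one row per effect: `term`, `statistic`, `df1`,
#'   `df2`, `p_value`.
#' @export
mixed_anova <- function(values, between = NULL) {
  stopifnot(all(c("subject", "within", "value") %in% names(values)))
  values <- as.data.frame(values)
  values$subject <- factor(values$subject)
  values$within <- factor(values$within)
  if (nlevels(values$within) != 2) {
    stop("within factor must have exactly 2 levels", call. = FALSE)
  }
  counts <- table(values$subject, values$within)
  bad <- rownames(counts)[apply(counts, 1, function(r) any(r != 1))]
  if (length(bad) > 0) {
    stop("subject(s) not observed exactly once at each within level: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  row_of <- function(tab, term) which(trimws(rownames(tab)) == term)
  ss_scale <- sum((values$value - mean(values$value))^2)

  if (is.null(between)) {
    fit <- aov(value ~ within + Error(subject), data = values)
    s <- summary(fit)
    tab <- s[["Error: Within"]][[1]]
    i <- row_of(tab, "within")
    j <- row_of(tab, "Residuals")
    f <- tab[i, "F value"]
    p <- tab[i, "Pr(>F)"]
    # an effect sum of squares at numerical zero is reported as F = 0
    if (!is.finite(f) || tab[i, "Sum Sq"] <= 1e-10 * max(ss_scale, 1e-300)) {
      f <- 0
      p <- 1
    }
    return(tibble::tibble(
      term = "within",
      statistic = f,
      df1 = tab[i, "Df"],
      df2 = tab[j, "Df"],
      p_value = p
    ))
  }

  subj <- levels(values$subject)
  if (!is.null(names(between))) {
    grp <- between[subj]
  } else {
    stopifnot(length(between) == length(subj))
    grp <- between
  }
  values$group <- factor(grp[match(values$subject, subj)])
  fit <- aov(value ~ group * within + Error(subject), data = values)
  s <- summary(fit)
  btab <- s[["Error: subject"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  grab <- function(tab, term) {
    i <- row_of(tab, term)
    j <- row_of(tab, "Residuals")
    f <- tab[i, "F value"]
    p <- tab[i, "Pr(>F)"]
    if (!is.finite(f) || tab[i, "Sum Sq"] <= 1e-10 * max(ss_scale, 1e-300)) {
      f <- 0
      p <- 1
    }
    tibble::tibble(term = term, statistic = f,
                   df1 = tab[i, "Df"], df2 = tab[j, "Df"],
                   p_value = p)
  }
  dplyr::bind_rows(
    grab(btab, "group"),
    grab(wtab, "within"),
    grab(wtab, "group:within")
  )
}
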