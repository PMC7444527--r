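#' Default decision-threshold grid
#'
#' The six half-integer thresholds that slide across the 7-point certainty
#' scale, from "very permissive" (-2.5) to "very strict" (2.5). Each value
#' lies strictly between adjacent scale steps so a graded rating is never
#' tied with a threshold.
#'
#' @return Numeric vector `c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)`.
#' @export
default_threshold_grid <- function() {
  c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
}

check_threshold_grid <- function(grid) {
  if (length(grid) < 1 || any(!is.finite(grid))) {
    stop("threshold grid must be finite and non-empty", call. = FALSE)
  }
  if (any(grid == round(grid))) {
    stop("thresholds must be non-integral (integer thresholds make ties ambiguous)",
         call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("threshold grid must be strictly increasing", call. = FALSE)
  }
  invisible(grid)
}

#' Binarize a graded rating at a decision threshold
#'
#' Converts certainty ratings to binary identity decisions: 1 ("same") when
#' the rating exceeds the threshold, 0 ("different") otherwise. At the
#' headline threshold 0.5, "not sure" (0) and everything below count as a
#' "different" determination.
#'
#' @param rating Integer rating(s) in \[-3, 3\].
#' @param theta A single non-integral threshold.
#' @return Integer vector of 0/1 decisions.
#' @export
binarize_rating <- function(rating, theta) {
  stopifnot(length(theta) == 1, is.finite(theta))
  if (theta == round(theta)) {
    stop("theta must be non-integral so ratings are never tied with it",
         call. = FALSE)
  }
  if (any(rating != round(rating))) {
    stop("ratings must be integers", call. = FALSE)
  }
  as.integer(rating > theta)
}

#' Hit, false-alarm, and accuracy rates at one threshold
#'
#' For a response set with `n` mated ("same") and `m` non-mated
#' ("different") trials, the true positive rate is the fraction of mated
#' trials rated above `theta`, the false positive rate the fraction of
#' non-mated trials rated above `theta`, and accuracy the trial-weighted
#' combination `(n * TPR + m * (1 - FPR)) / (n + m)`.
#'
#' @param records A validated response tibble (catch trials should already
#'   be screened out by the caller).
#' @param theta A single non-integral threshold.
#' @return One-row tibble: `theta`, `tpr`, `fpr`, `acc`, `n`, `m`.
#' @export
rates_at_threshold <- function(records, theta) {
  stopifnot(length(theta) == 1)
  if (theta == round(theta)) {
    stop("theta must be non-integral", call. = FALSE)
  }
  same <- records$rating[records$truth == "same"]
  diff <- records$rating[records$truth == "different"]
  if (length(same) == 0) {
    stop("no same-truth responses: rates undefined", call. = FALSE)
  }
  if (length(diff) == 0) {
    stop("no different-truth responses: rates undefined", call. = FALSE)
  }
  n <- length(same)
  m <- length(diff)
  tpr <- mean(same > theta)
  fpr <- mean(diff > theta)
  tibble::tibble(
    theta = theta, tpr = tpr, fpr = fpr,
    acc = (n * tpr + m * (1 - fpr)) / (n + m),
    n = n, m = m
  )
}

#' Sweep the threshold grid over a response set
#'
#' @param records A validated response tibble.
#' @param grid Strictly increasing non-integral thresholds
#'   (default [default_threshold_grid()]).
#' @return A tibble with one row per threshold, in grid order. TPR and FPR
#'   are non-increasing in the threshold.
#' @export
threshold_sweep <- function(records, grid = default_threshold_grid()) {
  check_threshold_grid(grid)
  dplyr::bind_rows(lapply(grid, function(th) rates_at_threshold(records, th)))
}

#' Pooled sensitivity and decision criterion
#'
#' Under the equal-variance Gaussian observer model,
#' `d' = z(TPR) - z(FPR)` measures the separation between the latent
#' evidence distributions for mated and non-mated pairs, and
#' `c = -(z(TPR) + z(FPR)) / 2` locates the decision criterion relative to
#' the unbiased midpoint (positive = conservative, i.e. biased toward
#' "different"). Both are undefined when either rate is 0 or 1; pool across
#' volunteers or use [corrected_rate()] first.
#'
#' @param tpr,fpr Rates strictly inside (0, 1); vectorized in parallel.
#' @param condition Optional label(s) carried through to the output.
#' @return A tibble: `condition`, `dprime`, `criterion`, `tpr`, `fpr`.
#' @export
dprime_criterion <- function(tpr, fpr, condition = NA_character_) {
  stopifnot(length(tpr) == length(fpr))
  if (any(tpr <= 0 | tpr >= 1 | fpr <= 0 | fpr >= 1)) {
    stop("d' and criterion are undefined when TPR or FPR is 0 or 1; ",
         "pool responses or apply corrected_rate()", call. = FALSE)
  }
  zt <- qnorm(tpr)
  zf <- qnorm(fpr)
  tibble::tibble(
    condition = rep_len(condition, length(tpr)),
    dprime = zt - zf,
    criterion = -(zt + zf) / 2,
    tpr = tpr, fpr = fpr
  )
}

#' Rate correction for degenerate counts
#'
#' The log-linear correction `(successes + 0.5) / (trials + 1)` keeps rates
#' strictly inside (0, 1), enabling per-subject signal detection metrics
#' where raw subject-level rates hit 0 or 1.
#'
#' @param successes,trials Non-negative counts with `successes <= trials`.
#' @param mode `"log_linear"` (default) or `"none"` (plain proportion).
#' @return Corrected proportion(s).
#' @export
corrected_rate <- function(successes, trials, mode = c("log_linear", "none")) {
  mode <- match.arg(mode)
  if (any(trials < 1) || any(successes < 0) || any(successes > trials)) {
    stop("need 0 <= successes <= trials and trials >= 1", call. = FALSE)
  }
  switch(mode,
    log_linear = (successes + 0.5) / (trials + 1),
    none = successes / trials
  )
}

#' Gaussian-assumption ROC fit in z-space
#'
#' Transforms each operating point to `(z(FPR), z(TPR))` with the standard
#' normal quantile function, fits the line `z(TPR) = I + S * z(FPR)` by
#' ordinary least squares, and reports the area under the fitted ROC,
#' `Az = Phi(I / sqrt(1 + S^2))`. Points with a rate of exactly 0 or 1 have
#' no finite z-transform and are dropped before fitting; at least two finite
#' points must remain. A non-positive fitted slope yields an improper ROC
#' and is flagged with a warning.
#'
#' @param points A tibble of operating points with columns `tpr` and `fpr`
#'   (e.g. from [threshold_sweep()]).
#' @return A list of class `roc_fit`: `intercept`, `slope`, `az`,
#'   `points` (the retained z-space points), `n_dropped`, `improper`.
#' @export
fit_roc_zspace <- function(points) {
  stopifnot(all(c("tpr", "fpr") %in% names(points)))
  finite <- points$tpr > 0 & points$tpr < 1 & points$fpr > 0 & points$fpr < 1
  kept <- points[finite, , drop = FALSE]
  if (nrow(kept) < 2) {
    stop("ROC fit needs at least 2 operating points strictly inside (0,1); got ",
         nrow(kept), call. = FALSE)
  }
  zf <- qnorm(kept$fpr)
  zt <- qnorm(kept$tpr)
  fit <- lm(zt ~ zf)
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  improper <- slope <= 0
  if (improper) {
    warning("fitted z-space slope is non-positive: improper ROC", call. = FALSE)
  }
  structure(list(
    intercept = intercept,
    slope = slope,
    az = pnorm(intercept / sqrt(1 + slope^2)),
    points = tibble::tibble(zfpr = zf, ztpr = zt,
                            theta = if ("theta" %in% names(kept)) kept$theta
                                    else NA_real_),
    n_dropped = sum(!finite),
    improper = improper
  ), class = "roc_fit")
}

#' @export
print.roc_fit <- function(x, ...) {
  cat(sprintf("z-space ROC fit: I = %.4f, S = %.4f, Az = %.4f (%d points%s)\n",
              x$intercept, x$slope, x$az, nrow(x$points),
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  if (x$improper) cat("  warning: non-positive slope (improper ROC)\n")
  invisible(x)
}

#' Per-volunteer rates at one threshold
#'
#' Convenience grouping used by the ANOVA layouts: accuracy, TPR and FPR per
#' volunteer (optionally split by prior label) at a single threshold.
#'
#' @param records A validated response tibble.
#' @param theta A single non-integral threshold.
#' @param by_label Split each volunteer's responses by `prior_label`?
#' @return A tibble keyed by `volunteer_id` (and `prior_label` when
#'   `by_label = TRUE`) with `variant`, `acc`, `tpr`, `fpr`, `n`, `m`.
#' @export
volunteer_rates <- function(records, theta = 0.5, by_label = FALSE) {
  if (theta == round(theta)) stop("theta must be non-integral", call. = FALSE)
  keys <- c("volunteer_id", "variant", if (by_label) "prior_label")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = sum(.data$truth == "same"),
      m = sum(.data$truth == "different"),
      tpr = mean(.data$rating[.data$truth == "same"] > theta),
      fpr = mean(.data$rating[.data$truth == "different"] > theta),
      acc = (sum(.data$rating[.data$truth == "same"] > theta) +
               sum(.data$rating[.data$truth == "different"] <= theta)) /
        dplyr::n(),
      .groups = "drop"
    )
}
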