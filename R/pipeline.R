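#' Analysis configuration
#'
#' Settings for the end-to-end analysis. The headline threshold (default
#' 0.5) separates responses expressing some confidence in "same person"
#' from the rest and must belong to the threshold grid; the full grid is
#' always also analysed.
#'
#' @param threshold_grid Strictly increasing non-integral thresholds.
#' @param headline_theta The single threshold used for the rate, ANOVA and
#'   d'/criterion tables.
#' @param bootstrap A [bootstrap_config()].
#' @param rule A [catch_rule()] for volunteer screening.
#' @param include_control_in_overall_roc Should the overall (collapsed) ROC
#'   fit include the control arm? Default `TRUE`.
#' @param per_subject_sdt Also compute per-volunteer d'/criterion with the
#'   log-linear rate correction? Default `FALSE` (pooled rates are the
#'   primary analysis because raw subject-level rates can hit 0 or 1).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(threshold_grid = default_threshold_grid(),
                            headline_theta = 0.5,
                            bootstrap = bootstrap_config(),
                            rule = catch_rule(),
                            include_control_in_overall_roc = TRUE,
                            per_subject_sdt = FALSE) {
  check_threshold_grid(threshold_grid)
  if (!headline_theta %in% threshold_grid) {
    stop("headline_theta must belong to the threshold grid", call. = FALSE)
  }
  structure(list(
    threshold_grid = threshold_grid,
    headline_theta = headline_theta,
    bootstrap = bootstrap,
    rule = rule,
    include_control_in_overall_roc = isTRUE(include_control_in_overall_roc),
    per_subject_sdt = isTRUE(per_subject_sdt)
  ), class = "analysis_config")
}

# prior-label condition of each record: control responses form the "none"
# condition; sourced responses split by their label
label_condition <- function(records) {
  ifelse(records$variant == "control", "none", records$prior_label)
}

boot_ci <- function(records, statistic, config, counter) {
  cfg <- config$bootstrap
  cfg$seed <- cfg$seed + counter
  bootstrap_statistic(records, statistic, cfg)
}

#' Run the full analysis
#'
#' Executes the whole workflow on a validated response table: catch-trial
#' screening; design summary; pooled accuracy/TPR/FPR with volunteer-level
#' bootstrap CIs by information source and by prior label; one-way and
#' repeated-measures ANOVA on per-volunteer rates; pooled d' and criterion
#' per prior-label condition with bootstrap CIs; threshold sweeps and
#' z-space ROC fits per condition plus an overall fit on collapsed data;
#' per-item rank tests with the across-item mean-shift summary; and, when a
#' volunteer profile table is supplied, chi-squared homogeneity tests of
#' demographic blocking and trust responses. Progress is logged as
#' stage-tagged counts only (no ratings), since response tables are
#' human-subjects data in real deployments.
#'
#' @param records A response tibble (catch trials still included).
#' @param volunteers Optional volunteer profile tibble
#'   (see [read_volunteer_table()]).
#' @param config An [analysis_config()].
#' @param quiet Suppress progress messages?
#' @return A list of class `analysis_report`; see the sections documented
#'   in [render_report()].
#' @export
run_full_analysis <- function(records, volunteers = NULL,
                              config = analysis_config(), quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  records <- validate_records(records)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }
  say("read", nrow(records), " records from ",
      length(unique(records$volunteer_id)), " volunteers")

  screened <- screen_catch_trials(records, config$rule)
  kept <- screened$kept
  say("screen", nrow(screened$excluded), " volunteer(s) excluded; ",
      nrow(kept), " experimental records retained")
  if (nrow(kept) == 0) stop("screening removed all records", call. = FALSE)

  design <- summarize_design(kept)
  theta <- config$headline_theta

  stat_for <- function(metric) {
    switch(metric,
      acc = function(r) rates_at_threshold(r, theta)$acc,
      tpr = function(r) rates_at_threshold(r, theta)$tpr,
      fpr = function(r) rates_at_threshold(r, theta)$fpr
    )
  }
  counter <- 0L
  rate_row <- function(r, label) {
    pooled <- rates_at_threshold(r, theta)
    cis <- lapply(c("acc", "fpr", "tpr"), function(metric) {
      counter <<- counter + 1L
      boot_ci(r, stat_for(metric), config, counter)
    })
    tibble::tibble(
      condition = label, n = length(unique(r$volunteer_id)),
      acc = pooled$acc, acc_lower = cis[[1]]$lower, acc_upper = cis[[1]]$upper,
      fpr = pooled$fpr, fpr_lower = cis[[2]]$lower, fpr_upper = cis[[2]]$upper,
      tpr = pooled$tpr, tpr_lower = cis[[3]]$lower, tpr_upper = cis[[3]]$upper
    )
  }

  # --- rates by information source (survey variant) ---
  say("rates", "pooled rates by source at theta = ", theta)
  source_levels <- intersect(c("control", "human_source", "computer_source"),
                             unique(kept$variant))
  rates_by_source <- dplyr::bind_rows(lapply(source_levels, function(v) {
    rate_row(kept[kept$variant == v, ], v)
  }))

  # --- rates by prior label condition ---
  cond <- label_condition(kept)
  cond_levels <- intersect(c("none", "same", "different"), unique(cond))
  rates_by_prior <- dplyr::bind_rows(lapply(cond_levels, function(cc) {
    rate_row(kept[cond == cc, ], cc)
  }))

  # --- ANOVA layouts on per-volunteer rates ---
  vr <- volunteer_rates(kept, theta)
  anova_source <- dplyr::bind_rows(lapply(c("acc", "fpr", "tpr"), function(mm) {
    res <- oneway_anova(split(vr[[mm]], vr$variant))
    res$metric <- mm
    res$effect <- "source"
    res
  }))
  sourced <- kept[kept$variant != "control", , drop = FALSE]
  anova_prior <- NULL
  if (nrow(sourced) > 0 &&
      length(unique(sourced$prior_label)) == 2) {
    vrl <- volunteer_rates(sourced, theta, by_label = TRUE)
    anova_prior <- dplyr::bind_rows(lapply(c("acc", "fpr", "tpr"), function(mm) {
      long <- tibble::tibble(subject = vrl$volunteer_id,
                             within = vrl$prior_label,
                             value = vrl[[mm]])
      res <- mixed_anova(long)
      res$metric <- mm
      res$effect <- "prior_label (within, pooled sources)"
      res
    }))
  }

  # --- pooled SDT per prior-label condition ---
  say("sdt", "pooled d'/criterion per prior-label condition")
  sdt_stat <- function(fun) function(r) {
    p <- rates_at_threshold(r, theta)
    if (p$tpr <= 0 || p$tpr >= 1 || p$fpr <= 0 || p$fpr >= 1) return(NA_real_)
    fun(dprime_criterion(p$tpr, p$fpr))
  }
  sdt_table <- dplyr::bind_rows(lapply(cond_levels, function(cc) {
    r <- kept[cond == cc, , drop = FALSE]
    pooled <- rates_at_threshold(r, theta)
    est <- dprime_criterion(pooled$tpr, pooled$fpr, condition = cc)
    counter <<- counter + 1L
    ci_d <- boot_ci(r, sdt_stat(function(x) x$dprime), config, counter)
    counter <<- counter + 1L
    ci_c <- boot_ci(r, sdt_stat(function(x) x$criterion), config, counter)
    tibble::tibble(
      condition = cc, n = length(unique(r$volunteer_id)),
      dprime = est$dprime, dprime_lower = ci_d$lower, dprime_upper = ci_d$upper,
      criterion = est$criterion, criterion_lower = ci_c$lower,
      criterion_upper = ci_c$upper
    )
  }))

  per_subject <- NULL
  if (config$per_subject_sdt) {
    vs <- volunteer_rates(kept, theta)
    tpr_c <- corrected_rate(round(vs$tpr * vs$n), vs$n)
    fpr_c <- corrected_rate(round(vs$fpr * vs$m), vs$m)
    per_subject <- dplyr::bind_cols(
      vs[c("volunteer_id", "variant")],
      dprime_criterion(tpr_c, fpr_c)[c("dprime", "criterion")]
    )
  }

  # --- threshold sweeps and ROC fits ---
  say("roc", "threshold sweep and z-space fits")
  sweep_conditions <- lapply(setNames(cond_levels, cond_levels), function(cc) {
    threshold_sweep(kept[cond == cc, , drop = FALSE], config$threshold_grid)
  })
  overall_set <- if (config$include_control_in_overall_roc) kept
                 else kept[kept$variant != "control", , drop = FALSE]
  sweep_conditions$overall <- threshold_sweep(overall_set, config$threshold_grid)
  roc_points <- dplyr::bind_rows(
    lapply(names(sweep_conditions), function(nm) {
      dplyr::mutate(sweep_conditions[[nm]], condition = nm, .before = 1)
    })
  )
  roc_fits <- dplyr::bind_rows(lapply(names(sweep_conditions), function(nm) {
    f <- fit_roc_zspace(sweep_conditions[[nm]])
    tibble::tibble(condition = nm, intercept = f$intercept, slope = f$slope,
                   az = f$az, n_points = nrow(f$points),
                   n_dropped = f$n_dropped, improper = f$improper)
  }))

  # --- per-item label-shift tests ---
  item_tests <- NULL
  shift_summary <- NULL
  if (nrow(sourced) > 0 && length(unique(sourced$prior_label)) == 2) {
    say("items", "per-item rank tests across prior labels")
    item_ids <- sort(unique(sourced$item_id))
    item_tests <- dplyr::bind_rows(lapply(item_ids, function(it) {
      a <- sourced$rating[sourced$item_id == it & sourced$prior_label == "same"]
      b <- sourced$rating[sourced$item_id == it &
                            sourced$prior_label == "different"]
      res <- rank_sum_item_test(a, b)
      tibble::tibble(item_id = it, n_same_label = length(a),
                     n_diff_label = length(b),
                     mean_same_label = mean(a), mean_diff_label = mean(b),
                     statistic = res$statistic, p_value = res$p_value,
                     significant = res$p_value < 0.05)
    }))
    item_tests$p_holm <- stats::p.adjust(item_tests$p_value, method = "holm")
    shift_summary <- item_shift_summary(item_tests$mean_same_label,
                                        item_tests$mean_diff_label)
  }

  # --- demographics and trust ---
  blocking <- NULL
  trust <- NULL
  if (!is.null(volunteers)) {
    say("demographics", "blocking and trust chi-squared tests")
    vol <- kept |>
      dplyr::distinct(.data$volunteer_id, .data$variant) |>
      dplyr::inner_join(volunteers, by = "volunteer_id")
    blocking <- dplyr::bind_rows(lapply(
      c("gender", "age_bin", "race"),
      function(dim) {
        sub <- vol[!is.na(vol[[dim]]), , drop = FALSE]
        tab <- table(sub[[dim]], sub$variant)
        res <- chi_squared_test(tab)
        tibble::tibble(dimension = dim, statistic = res$statistic,
                       df = res$df, p_value = res$p_value)
      }
    ))
    tr <- vol[vol$trust_response != "missing", , drop = FALSE]
    trust_counts <- as.data.frame.matrix(table(tr$variant, tr$trust_response))
    yes_tab <- cbind(yes = tapply(tr$trust_response == "yes", tr$variant, sum),
                     not_yes = tapply(tr$trust_response != "yes", tr$variant,
                                      sum))
    trust_test <- chi_squared_test(yes_tab)
    trust <- list(counts = tibble::as_tibble(trust_counts,
                                             rownames = "variant"),
                  yes_test = trust_test)
  }

  say("done", "report assembled")
  structure(list(
    design = design,
    excluded = screened$excluded,
    unscreenable = screened$unscreenable,
    rates_by_source = rates_by_source,
    rates_by_prior = rates_by_prior,
    anova = dplyr::bind_rows(anova_source, anova_prior),
    sdt = sdt_table,
    per_subject_sdt = per_subject,
    roc_points = roc_points,
    roc_fits = roc_fits,
    item_tests = item_tests,
    shift_summary = shift_summary,
    blocking = blocking,
    trust = trust,
    meta = list(
      headline_theta = theta,
      threshold_grid = config$threshold_grid,
      bootstrap_B = config$bootstrap$B,
      bootstrap_seed = config$bootstrap$seed,
      n_records_read = nrow(records),
      n_volunteers_read = length(unique(records$volunteer_id)),
      n_excluded = nrow(screened$excluded),
      n_analyzed = length(unique(kept$volunteer_id)),
      package_version = as.character(utils::packageVersion("matchbias"))
    )
  ), class = "analysis_report")
}

# round-half-even presentation rounding (R's round() is IEC 60559 half-even)
present <- function(x, digits = 2) {
  if (is.numeric(x)) round(x, digits) else x
}

#' Write an analysis report to disk
#'
#' One file per report section, with stable column order. Numeric values
#' are written at full precision; each CSV section also gets a
#' `*_presentation.csv` copy rounded to 2 decimals by round-half-even, the
#' style used in summary tables. JSON output serializes the full-precision
#' sections in one `report.json`.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed; must be writable).
#' @param formats Subset of `c("csv", "json")`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "analysis_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }

  sections <- list(
    table2_blocking = report$blocking,
    trust = if (!is.null(report$trust)) report$trust$counts,
    table4_rates_by_source = report$rates_by_source,
    table5_rates_by_prior = report$rates_by_prior,
    table6_sdt = report$sdt,
    fig4_item_tests = report$item_tests,
    fig5_roc_points = report$roc_points,
    fig5_roc_fits = report$roc_fits,
    anova = report$anova,
    exclusions = report$excluded
  )
  sections <- Filter(Negate(is.null), sections)

  paths <- character(0)
  if ("csv" %in% formats) {
    for (nm in names(sections)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(as.data.frame(sections[[nm]]), p, row.names = FALSE)
      pp <- file.path(dir, paste0(nm, "_presentation.csv"))
      write.csv(as.data.frame(lapply(sections[[nm]], present)), pp,
                row.names = FALSE)
      paths <- c(paths, p, pp)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    payload <- c(sections, list(meta = report$meta))
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
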