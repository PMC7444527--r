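#' Simulation configuration for the synthetic survey
#'
#' Parameters of the generative model: equal-variance Gaussian observers
#' whose latent face-similarity evidence is N(d', 1) for mated pairs and
#' N(0, 1) for non-mated pairs, mapped to the 7-point certainty scale by six
#' ordered category boundaries. A prior identity label shifts every boundary
#' by `-delta/2` ("same" label) or `+delta/2` ("different" label), moving
#' the decision criterion without touching d'. Per-volunteer sensitivity is
#' drawn from N(`mu_dprime`, `sigma_dprime`^2) truncated at 0.
#'
#' Defaults mirror the study design: three survey variants (control,
#' human source, computer source) of ~120 volunteers each, 12 experimental
#' pairs balanced 6 mated / 6 non-mated, 2 celebrity catch pairs, and two
#' counterbalanced versions so each experimental pair appears under both
#' labels. `delta = 0.22` is the criterion gap the analysis is designed to
#' detect; `mu_dprime = 1.4` matches typical pooled sensitivity on a
#' difficult unfamiliar-face task. Boundaries default to six points spaced
#' `boundary_spacing` apart, symmetric about the midpoint `mu_dprime / 2`
#' (so the control-condition headline criterion is `boundary_spacing / 2`).
#'
#' @param n_volunteers_per_variant Volunteers per survey variant (default 120).
#' @param n_same_items,n_diff_items Mated / non-mated experimental pairs
#'   (default 6 and 6).
#' @param n_catch Celebrity catch pairs, split as evenly as possible between
#'   mated and non-mated (default 2).
#' @param mu_dprime,sigma_dprime Population mean and between-rater sd of d'
#'   (defaults 1.4, 0.3).
#' @param boundary_spacing Latent-scale distance between adjacent category
#'   boundaries (default 0.4).
#' @param boundaries Optional explicit vector of 6 strictly increasing
#'   boundaries, overriding the symmetric default.
#' @param delta Label-induced criterion shift in latent units (default 0.22).
#' @param catch_separation Latent separation between mated and non-mated
#'   celebrity pairs (default 6, i.e. essentially error-free for a
#'   compliant observer).
#' @param catch_fail_rate Probability that a volunteer is planted with a
#'   catch-trial failure (default 0).
#' @param seed Integer seed making the whole survey reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_volunteers_per_variant = 120,
                       n_same_items = 6, n_diff_items = 6, n_catch = 2,
                       mu_dprime = 1.4, sigma_dprime = 0.3,
                       boundary_spacing = 0.4, boundaries = NULL,
                       delta = 0.22, catch_separation = 6,
                       catch_fail_rate = 0, seed = 1L) {
  stopifnot(
    n_volunteers_per_variant >= 1, n_same_items >= 1, n_diff_items >= 1,
    n_catch >= 0, sigma_dprime >= 0, boundary_spacing > 0,
    catch_fail_rate >= 0, catch_fail_rate <= 1
  )
  if (mu_dprime <= 0 && sigma_dprime == 0) {
    stop("mu_dprime must be positive when sigma_dprime is 0", call. = FALSE)
  }
  if (is.null(boundaries)) {
    boundaries <- mu_dprime / 2 +
      boundary_spacing * c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  }
  if (length(boundaries) != 6 || is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be 6 strictly increasing values", call. = FALSE)
  }
  structure(list(
    n_volunteers_per_variant = as.integer(n_volunteers_per_variant),
    n_same_items = as.integer(n_same_items),
    n_diff_items = as.integer(n_diff_items),
    n_catch = as.integer(n_catch),
    mu_dprime = mu_dprime, sigma_dprime = sigma_dprime,
    boundaries = boundaries, delta = delta,
    catch_separation = catch_separation,
    catch_fail_rate = catch_fail_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Category boundaries with a prescribed decision criterion
#'
#' Returns six boundaries spaced `spacing` apart whose headline boundary
#' (the one separating "not sure" from "somewhat certain same", i.e. the
#' threshold-0.5 decision) sits at `d'/2 + criterion`, so the pooled
#' criterion estimate at threshold 0.5 recovers `criterion`.
#'
#' @param dprime Generating sensitivity.
#' @param criterion Target decision criterion at the headline threshold.
#' @param spacing Distance between adjacent boundaries (default 0.4).
#' @return Numeric vector of 6 strictly increasing boundaries.
#' @export
rating_boundaries <- function(dprime, criterion = 0.2, spacing = 0.4) {
  dprime / 2 + spacing * c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5) +
    (criterion - spacing / 2)
}

# Map latent evidence to ratings -3..3 given a boundary matrix (one row per
# observation) or a single boundary vector.
evidence_to_rating <- function(evidence, boundaries) {
  if (is.matrix(boundaries)) {
    stopifnot(nrow(boundaries) == length(evidence), ncol(boundaries) == 6)
    r <- rowSums(evidence > boundaries)
  } else {
    r <- findInterval(evidence, boundaries)
  }
  as.integer(r - 3L)
}

#' Simulate ratings for one condition
#'
#' Low-level generator: draws `n_same` mated and `n_diff` non-mated latent
#' evidence values for a single observer/condition and maps them through
#' the category boundaries. Used directly for condition-level simulations
#' (e.g. comparing fitted Az across conditions) and internally by
#' [simulate_survey()].
#'
#' @param n_same,n_diff Number of mated / non-mated trials.
#' @param dprime Observer sensitivity.
#' @param boundaries Vector of 6 strictly increasing category boundaries.
#' @return A tibble with columns `truth` and `rating`.
#' @export
simulate_rating_set <- function(n_same, n_diff, dprime, boundaries) {
  stopifnot(length(boundaries) == 6, !is.unsorted(boundaries, strictly = TRUE))
  tibble::tibble(
    truth = rep(c("same", "different"), c(n_same, n_diff)),
    rating = evidence_to_rating(
      rnorm(n_same + n_diff, mean = rep(c(dprime, 0), c(n_same, n_diff))),
      boundaries
    )
  )
}

#' Draw the rater population and design assignment
#'
#' Assigns volunteers to the three survey variants, counterbalances the two
#' versions within the sourced variants, draws per-volunteer d' from the
#' truncated normal population, and flags volunteers planted with a
#' catch-trial failure. The returned ground truth, together with
#' [simulate_survey()], regenerates the response table bit-identically.
#'
#' @param config A [sim_config()].
#' @return A list of class `ground_truth`: `volunteers` (tibble with
#'   `volunteer_id`, `variant`, `version`, `dprime`, `catch_fail`) and
#'   `config`.
#' @export
simulate_raters <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nv <- config$n_volunteers_per_variant
  variants <- rep(VARIANT_LEVELS, each = nv)
  n <- length(variants)
  version <- ifelse(variants == "control", "none",
                    as.character(1L + (seq_len(n) %% 2L)))

  if (config$sigma_dprime == 0) {
    d <- rep(config$mu_dprime, n)
  } else {
    # truncated-at-zero normal via inverse CDF
    p0 <- pnorm(0, config$mu_dprime, config$sigma_dprime)
    d <- qnorm(p0 + runif(n) * (1 - p0), config$mu_dprime, config$sigma_dprime)
  }

  structure(list(
    volunteers = tibble::tibble(
      volunteer_id = sprintf("V%04d", seq_len(n)),
      variant = variants,
      version = version,
      dprime = d,
      catch_fail = runif(n) < config$catch_fail_rate
    ),
    config = config
  ), class = "ground_truth")
}

# Item roster implied by a sim_config: experimental items s01.., d01.., catch
# items c1 (mated), c2 (non-mated), ...
item_roster <- function(config) {
  items <- tibble::tibble(
    item_id = c(sprintf("s%02d", seq_len(config$n_same_items)),
                sprintf("d%02d", seq_len(config$n_diff_items))),
    truth = rep(c("same", "different"),
                c(config$n_same_items, config$n_diff_items)),
    is_catch = FALSE
  )
  if (config$n_catch > 0) {
    n_catch_same <- ceiling(config$n_catch / 2)
    items <- dplyr::bind_rows(items, tibble::tibble(
      item_id = sprintf("c%d", seq_len(config$n_catch)),
      truth = rep(c("same", "different"),
                  c(n_catch_same, config$n_catch - n_catch_same)),
      is_catch = TRUE
    ))
  }
  # version-1 label assignment: first half of each truth class told "same",
  # second half told "different"; version 2 flips it
  half_s <- ceiling(config$n_same_items / 2)
  half_d <- ceiling(config$n_diff_items / 2)
  label_v1 <- rep("none", nrow(items))
  es <- which(items$truth == "same" & !items$is_catch)
  ed <- which(items$truth == "different" & !items$is_catch)
  label_v1[es] <- rep(c("same", "different"),
                      c(half_s, length(es) - half_s))
  label_v1[ed] <- rep(c("same", "different"),
                      c(half_d, length(ed) - half_d))
  items$label_v1 <- label_v1
  items$label_v2 <- ifelse(label_v1 == "none", "none",
                           ifelse(label_v1 == "same", "different", "same"))
  items
}

#' Generate the synthetic response table
#'
#' For every volunteer x item, draws latent evidence (mean d' for mated
#' experimental pairs, 0 for non-mated; catch pairs sit `catch_separation`
#' apart around the volunteer's boundary midpoint) and maps it through the
#' category boundaries, shifted by `-delta/2` when the item is labelled
#' "same" and `+delta/2` when labelled "different". Control volunteers see
#' no labels. Volunteers flagged `catch_fail` have their mated catch
#' response overwritten with a clearly incorrect rating (-2).
#'
#' @param truth A `ground_truth` from [simulate_raters()].
#' @return A validated response tibble in canonical order.
#' @export
simulate_survey <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  config <- truth$config
  set.seed(config$seed + 1L)

  items <- item_roster(config)
  grid <- tidyr::crossing(truth$volunteers, items)
  grid$prior_label <- dplyr::case_when(
    grid$is_catch | grid$variant == "control" ~ "none",
    grid$version == "1" ~ grid$label_v1,
    TRUE ~ grid$label_v2
  )

  mid <- config$mu_dprime / 2  # boundaries are anchored to the population
  latent_mean <- ifelse(
    grid$is_catch,
    mid + ifelse(grid$truth == "same", 1, -1) * config$catch_separation / 2,
    ifelse(grid$truth == "same", grid$dprime, 0)
  )
  shift <- dplyr::case_when(
    grid$prior_label == "same" ~ -config$delta / 2,
    grid$prior_label == "different" ~ config$delta / 2,
    TRUE ~ 0
  )
  evidence <- rnorm(nrow(grid), latent_mean, 1)
  # a boundary shift of +s is equivalent to comparing (evidence - s) to the
  # unshifted boundaries
  rating <- evidence_to_rating(evidence - shift, config$boundaries)

  # planted catch failures: wrong-signed, confident response on the mated pair
  plant <- grid$catch_fail & grid$is_catch & grid$truth == "same"
  rating[plant] <- -2L

  records <- tibble::tibble(
    volunteer_id = grid$volunteer_id,
    variant = grid$variant,
    version = grid$version,
    item_id = grid$item_id,
    truth = grid$truth,
    prior_label = grid$prior_label,
    rating = rating,
    is_catch = grid$is_catch
  ) |>
    dplyr::arrange(.data$volunteer_id, .data$item_id)
  validate_records(records)
}

#' Small deterministic fixture table
#'
#' A <= 200-row synthetic response table exercising every enum value, both
#' survey versions, passing catch trials, and exactly one planted catch
#' failure (volunteer `V0001`). Intended for examples and fast tests.
#'
#' @return A validated response tibble (12 volunteers x 14 items = 168 rows).
#' @export
fixture_small <- function() {
  cfg <- sim_config(n_volunteers_per_variant = 4, seed = 207L)
  records <- simulate_survey(simulate_raters(cfg))
  fail <- records$volunteer_id == "V0001" & records$item_id == "c1"
  records$rating[fail] <- -2L
  records
}

#' Deterministic volunteer profiles for the small fixture
#'
#' Synthetic demographics and trust responses matching [fixture_small()]'s
#' twelve volunteers, cycling through every category level.
#'
#' @return A tibble with one row per fixture volunteer.
#' @export
fixture_small_volunteers <- function() {
  ids <- sprintf("V%04d", 1:12)
  tibble::tibble(
    volunteer_id = ids,
    gender = rep(c("female", "male"), 6),
    age_bin = rep(AGE_BINS, 2),
    race = rep(c("black", "white", "other"), 4),
    trust_response = rep(c("yes", "yes", "no", "not_sure"), 3)
  )
}
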