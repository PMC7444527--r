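#!/usr/bin/env Rscript

# Stage 1: generate the synthetic survey.
#
# Emulates the nested design: three survey variants (control, human source,
# computer source), two counterbalanced versions, 12 experimental face pairs
# (6 mated / 6 non-mated), 2 celebrity catch pairs. 126 volunteers per
# variant enter; about 8% carry a planted catch-trial failure, mirroring the
# exclusion fraction a strict screening rule produces in practice, so the
# screening stage has real work to do. Volunteer demographics are sampled
# exchangeably (the generative model makes no demographic claims).

suppressPackageStartupMessages(library(matchbias))

dir.create("results", showWarnings = FALSE)
seed <- 2019L

cfg <- sim_config(
  n_volunteers_per_variant = 126,
  delta = 0.22,          # label-induced criterion shift (latent units)
  mu_dprime = 1.4,       # population sensitivity
  sigma_dprime = 0.3,    # between-rater spread
  catch_fail_rate = 0.08,
  seed = seed
)
truth <- simulate_raters(cfg)
records <- simulate_survey(truth)
write_response_table(records, "results/responses.csv")

# exchangeable demographic profiles and trust responses
set.seed(seed + 2L)
vols <- truth$volunteers
profiles <- tibble::tibble(
  volunteer_id = vols$volunteer_id,
  gender = sample(c("female", "male"), nrow(vols), replace = TRUE),
  age_bin = sample(c("18-25", "26-35", "36-45", "46-55", "56-65", "65+"),
                   nrow(vols), replace = TRUE,
                   prob = c(0.06, 0.31, 0.19, 0.19, 0.16, 0.09)),
  race = sample(c("black", "white", "other"), nrow(vols), replace = TRUE,
                prob = c(0.45, 0.36, 0.19)),
  trust_response = sample(c("yes", "no", "not_sure"), nrow(vols),
                          replace = TRUE, prob = c(0.60, 0.12, 0.28))
)
utils::write.csv(profiles, "results/volunteers.csv", row.names = FALSE)

# ground truth kept for the recovery stage
jsonlite::write_json(
  list(mu_dprime = cfg$mu_dprime, sigma_dprime = cfg$sigma_dprime,
       delta = cfg$delta, boundaries = cfg$boundaries, seed = cfg$seed,
       n_planted_failures = sum(vols$catch_fail)),
  "results/ground_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d responses from %d volunteers (%d planted catch failures)\n",
            nrow(records), nrow(vols), sum(vols$catch_fail)))
cat("wrote results/responses.csv, results/volunteers.csv, results/ground_truth.json\n")
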