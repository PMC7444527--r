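#!/usr/bin/env Rscript

# Stage 2: validate, screen on catch trials, and summarize the design.
#
# A volunteer is dropped when any celebrity catch-pair response has the
# wrong sign or is "not sure"; the celebrity pairs themselves leave the
# analysis set here.

suppressPackageStartupMessages(library(matchbias))

records <- read_response_table("results/responses.csv")
screened <- screen_catch_trials(records, catch_rule(unsure_fails = TRUE))

design <- summarize_design(screened$kept)
print(design)

utils::write.csv(as.data.frame(screened$excluded), "results/exclusions.csv",
                 row.names = FALSE)
write_response_table(screened$kept, "results/responses_screened.csv")

cat(sprintf("read %d volunteers; excluded %d; %d analyzed\n",
            length(unique(records$volunteer_id)),
            nrow(screened$excluded),
            length(unique(screened$kept$volunteer_id))))
cat("wrote results/exclusions.csv, results/responses_screened.csv\n")
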