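# Small record tables built in code.

make_records <- function(volunteer_id, variant = "control", version = "none",
                         item_id, truth, prior_label = "none", rating,
                         is_catch = FALSE) {
  tibble::tibble(
    volunteer_id = volunteer_id, variant = variant, version = version,
    item_id = item_id, truth = truth, prior_label = prior_label,
    rating = as.integer(rating), is_catch = is_catch
  )
}

# One control volunteer with given experimental ratings plus perfect catch
# responses (c1 mated rated +3, c2 non-mated rated -3).
control_volunteer <- function(id, same_ratings, diff_ratings,
                              catch_ratings = c(3L, -3L)) {
  dplyr::bind_rows(
    make_records(id, item_id = sprintf("s%02d", seq_along(same_ratings)),
                 truth = "same", rating = same_ratings),
    make_records(id, item_id = sprintf("d%02d", seq_along(diff_ratings)),
                 truth = "different", rating = diff_ratings),
    make_records(id, item_id = c("c1", "c2"),
                 truth = c("same", "different"),
                 rating = catch_ratings, is_catch = TRUE)
  )
}

# The worked 8-response toy set: same {3,1,0,-2}, different {-3,-1,2,0}.
toy_records <- function() {
  dplyr::bind_rows(
    make_records("T1", item_id = sprintf("s%02d", 1:4), truth = "same",
                 rating = c(3, 1, 0, -2)),
    make_records("T1", item_id = sprintf("d%02d", 1:4), truth = "different",
                 rating = c(-3, -1, 2, 0))
  )
}
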