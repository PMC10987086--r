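# Shared fixtures, built in code at test time.

# A tiny hand-written trial table: 2 participants x 2 targets x 3 trials.
hand_trials <- function() {
  tibble::tibble(
    participant_id = rep(c("P1", "P2"), each = 6),
    condition = "fast",
    target = rep(rep(c(8, 16), each = 3), 2),
    response_count = as.integer(c(
      8, 10, 12,   # P1 @ 8:  mean 10, sd 2, wf 0.2
      14, 16, 18,  # P1 @ 16: mean 16, sd 2, wf 0.125
      7, 8, 9,     # P2 @ 8:  mean 8, sd 1, wf 0.125
      15, 16, 17   # P2 @ 16: mean 16, sd 1, wf 0.0625
    )),
    response_duration = 0
  ) |>
    dplyr::mutate(response_duration = response_count / 4)
}

# Canonical two-channel study configuration (simulation display condition).
two_channel_config <- function(...) {
  channel_config(2, fwhm_octaves = 1.45, ...)
}

# A wf_matrix built directly from a numeric matrix.
wfm_from_matrix <- function(values, targets, condition = "fast") {
  new_wf_matrix(values, sprintf("P%02d", seq_len(nrow(values))), targets, condition)
}

# Independent two-pass Pearson correlation (oracle for cor()-based paths).
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
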