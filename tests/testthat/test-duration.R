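test_that("duration targets are mean response durations per number target", {
  # constant rate and perfect counts: durations are exactly target / rate
  targets <- numchan_targets()
  trials <- tidyr::expand_grid(participant_id = c("P1", "P2"),
                               target = targets, rep = 1:3) |>
    dplyr::mutate(condition = "fast",
                  response_count = as.integer(target),
                  response_duration = target / 4)
  dt <- derive_duration_targets(trials)
  expect_equal(nrow(dt), 22L)
  expect_equal(dt$duration, rep(targets / 4, 2))
  expect_equal(dt$rank[dt$participant_id == "P1"], 1:11)
  # ranks order by target, and unit rescaling is equivariant
  ms <- dplyr::mutate(trials, response_duration = response_duration * 1000)
  expect_equal(derive_duration_targets(ms)$duration, dt$duration * 1000)
  # missing cells drop the participant
  gap <- dplyr::filter(trials, !(participant_id == "P1" & target == 8))
  expect_warning(d2 <- derive_duration_targets(gap), "P1")
  expect_equal(unique(d2$participant_id), "P2")
})

test_that("monotone targets give monotone duration targets under unbiased reproduction", {
  cfg <- two_channel_config(n_reps = 200)
  trials <- simulate_cohort_trials(cfg, 6, seed = 8, rate_sd = 0)
  dt <- derive_duration_targets(trials)
  ok <- dt |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(monotone = all(diff(duration) > 0))
  expect_true(all(ok$monotone))
})

test_that("the packaged duration-target table replays correctly", {
  tab <- duration_targets_table()
  expect_equal(nrow(tab), 99L)  # 9 participants x 11 ranks
  s1 <- tab$duration[tab$participant_id == "S1"]
  expect_equal(s1, c(3, 4, 4.4, 5.1, 5.7, 6.8, 7.8, 8.8, 10.2, 12, 12.9))
  expect_true(all(tab$duration > 0))
  # non-decreasing with rank for every participant
  mono <- tab |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(ok = all(diff(duration) >= 0))
  expect_true(all(mono$ok))
  # a fixture replay: trials whose mean durations equal S1's row derive back to it
  trials <- tidyr::expand_grid(target = numchan_targets(), rep = 1:2) |>
    dplyr::mutate(participant_id = "S1", condition = "slow",
                  response_count = 1L,
                  response_duration = rep(s1, each = 2))
  expect_equal(derive_duration_targets(trials)$duration, s1)
  # round-trip through the Table-1 CSV layout
  path <- withr::local_tempfile(fileext = ".csv")
  write_duration_targets(tab, path)
  expect_equal(read_duration_targets(path), tab)
})

test_that("the duration pipeline reuses the number-task estimators unchanged", {
  # same values carried in both columns: identical statistics either way
  set.seed(5)
  trials <- tidyr::expand_grid(participant_id = c("P1", "P2"),
                               target = c(8, 16), rep = 1:10) |>
    dplyr::mutate(condition = "duration",
                  response_count = as.integer(round(rnorm(40, target, 2))),
                  response_duration = as.numeric(response_count))
  cn <- remove_outliers(trials, value = response_count)
  cd <- remove_outliers(trials, value = response_duration)
  expect_equal(cleaning_report(cn)$n_removed, cleaning_report(cd)$n_removed)
  sn <- reproduction_stats(cn, value = response_count)
  sd_ <- reproduction_stats(cd, value = response_duration)
  expect_equal(sn$wf, sd_$wf, tolerance = 1e-12)
})

test_that("task precision comparison reports exact paired differences", {
  cfg <- two_channel_config()
  num <- simulate_cohort(cfg, 9, seed = 31)
  # identical matrices: all differences zero
  same <- compare_task_precision(num, num)
  expect_true(all(tidy(same)$difference == 0))
  # constructed offset: mean difference exactly 0.08
  dur <- new_wf_matrix(wf_values(num) + 0.08, num$participant_id,
                       wf_targets(num), "duration")
  cmp <- compare_task_precision(num, dur)
  expect_equal(cmp$mean_difference, 0.08, tolerance = 1e-12)
  expect_equal(cmp$mean_wf_duration - cmp$mean_wf_number, 0.08, tolerance = 1e-12)
  expect_equal(glance(cmp)$n_participants, 9L)
  # participant order must not matter, but participant sets must match
  dur_shuffled <- new_wf_matrix(wf_values(dur)[9:1, ], dur$participant_id[9:1],
                                wf_targets(dur), "duration")
  expect_equal(compare_task_precision(num, dur_shuffled)$mean_difference, 0.08,
               tolerance = 1e-12)
  other <- new_wf_matrix(wf_values(num), paste0("X", 1:9), wf_targets(num), "duration")
  expect_error(compare_task_precision(num, other), "same participants")
})
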