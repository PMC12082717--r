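test_that("EDF write/read round-trips the signal within quantization", {
  rec <- make_noise_rec(20, n_ch = 2, seed = 4, labels = c("Fp1", "O2"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path, phys_max = 400)
  back <- read_recording(path)
  expect_equal(back$channel_labels, c("Fp1", "O2"))
  expect_equal(back$fs, 256)
  q <- 800 / 65535  # quantization step for the written physical range
  expect_lt(max(abs(back$signal - rec$signal[seq_len(nrow(back$signal)), ])),
            q)
  expect_true(all(is.finite(back$transducer_max)))
})

test_that("non-EEG channels are dropped by the label filter", {
  rec <- make_noise_rec(10, n_ch = 4, seed = 5,
                        labels = c("EEG Fp1", "EEG O2", "ECG", "EMG chin"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path, phys_max = 400)
  back <- read_recording(path)
  expect_equal(back$channel_labels, c("Fp1", "O2"))
  all_ch <- read_recording(path, drop_non_eeg = FALSE)
  expect_equal(ncol(all_ch$signal), 4L)
})

test_that("truncated or missing EDF files raise format errors", {
  expect_error(read_recording(file.path(tempdir(), "nope.edf")), "not found")
  rec <- make_noise_rec(10, n_ch = 1, seed = 6)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path, phys_max = 400)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  trunc_path <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:(length(raw) %/% 2)], trunc_path)
  expect_error(read_recording(trunc_path), "truncated")
  short_path <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:100], short_path)
  expect_error(read_recording(short_path), "truncated|valid")
})

test_that("noisy-record screen pools channels and is strict at 10%", {
  n <- 1000
  base <- matrix(1, n, 2)
  rec_all <- eeg_recording(base * 1.01 * 100, 256, c("a", "b"),
                           transducer_max = 100)
  expect_true(flag_noisy(rec_all))

  sig <- base
  sig[1:50, 1] <- 150  # 50 of 2000 pooled samples = 2.5%
  rec_few <- eeg_recording(sig, 256, c("a", "b"), transducer_max = 100)
  expect_false(flag_noisy(rec_few))

  sig10 <- base
  sig10[1:100, 1] <- 150
  sig10[1:100, 2] <- 150  # exactly 10.0% pooled
  rec_edge <- eeg_recording(sig10, 256, c("a", "b"), transducer_max = 100)
  expect_false(flag_noisy(rec_edge))

  # channel-order invariance
  perm <- eeg_recording(sig10[, c(2, 1)], 256, c("b", "a"),
                        transducer_max = 100)
  expect_identical(flag_noisy(perm), flag_noisy(rec_edge))
})

test_that("seizure inclusion and cluster rules follow onset timing", {
  dur <- 24 * 3600
  ev <- seizure_events(c(9, 11) * 3600, c(9, 11) * 3600 + 60)
  kept <- select_seizures(ev, dur)
  expect_equal(kept$onset_s, 9 * 3600)  # 11 h onset is in the 9 h cluster

  ev2 <- seizure_events(c(9, 22.5) * 3600, c(9, 22.5) * 3600 + 60)
  expect_equal(nrow(select_seizures(ev2, dur)), 2L)  # 13.5 h apart

  ev3 <- seizure_events(5 * 3600, 5 * 3600 + 60)
  expect_equal(nrow(select_seizures(ev3, dur)), 0L)  # < 8 h of pre-onset data

  # idempotence
  once <- select_seizures(ev2, dur)
  expect_identical(select_seizures(once, dur), once)
})

test_that("sidecar annotations round-trip through JSON", {
  ev <- seizure_events(c(30000, 80000), c(30060, 80100))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations("rec-1", ev, path)
  back <- read_annotations(path)
  expect_equal(back$record_id, "rec-1")
  expect_equal(back$events$onset_s, ev$onset_s)
  expect_equal(back$events$offset_s, ev$offset_s)
})

test_that("Siena seizure-list files parse with midnight wrap", {
  txt <- c(
    "Patient: PN00",
    "Registration start time: 19.00.44",
    "Registration end time: 07.48.26",
    "Seizure n 1",
    "Seizure start time: 21.51.02",
    "Seizure end time: 21.52.07",
    "Seizure n 2",
    "Seizure start time: 01.10.00",
    "Seizure end time: 01.11.30"
  )
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, path)
  ev <- read_siena_annotations(path)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$onset_s[1], (21 - 19) * 3600 + 50 * 60 + 18)
  # second seizure is past midnight
  expect_equal(ev$onset_s[2], (24 - 19) * 3600 - 44 + 1 * 3600 + 10 * 60)
  expect_true(all(ev$offset_s > ev$onset_s))
})

test_that("reports serialize to CSV and JSON including edge cases", {
  empty <- list(rows = preictalr:::.empty_row()[0, ])
  prefix <- file.path(withr::local_tempdir(), "rep")
  write_report(empty, prefix)
  csv <- read.csv(paste0(prefix, ".csv"))
  expect_equal(nrow(csv), 0L)
  expect_true(all(c("patient_id", "detected", "preictal_duration_min")
                  %in% names(csv)))

  row <- preictalr:::.empty_row("4", "1")
  row$detected <- TRUE
  row$preictal_start_min_before_onset <- 30
  row$preictal_duration_min <- 30
  row$channel <- "O2"
  row$channels_selected <- "O2;O1;Pz"
  row$top3_features <- "spectral_entropy;hjorth_mobility;delta_power"
  nd <- preictalr:::.empty_row("5", "1")  # not detected marker row
  rep2 <- list(rows = rbind(row, nd))
  write_report(rep2, prefix)
  back <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(back$rows$channels_selected[1], "O2;O1;Pz")
  expect_equal(back$rows$detected, c(TRUE, FALSE))
  expect_equal(back$summary$n_detected, 1L)
})
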