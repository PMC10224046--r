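test_that("NCC of the template against itself is +1, against its negation -1", {
  tpl_vec <- c(0.2, 1.5, -0.8, 0.4, -0.1)
  rec <- signal_record(tpl_vec, rep(0, 5), fs = 100)
  tpl <- select_template(rec, c(0, 0.04), case_label = 1)
  expect_equal(compute_ncc(tpl_vec, tpl, fs = 100)$values, 1)
  expect_equal(compute_ncc(-tpl_vec, tpl, fs = 100)$values, -1)
})

test_that("compute_ncc matches the literal definition on the worked example", {
  s <- c(1, 3, 2, 5, 4, 1)
  tpl <- c(3, 2, 5)
  got <- compute_ncc(s, tpl, fs = 1)$values
  expect_length(got, 4)
  expect_equal(got, ncc_oracle(s, tpl), tolerance = 1e-12)
})

test_that("compute_ncc matches the literal-definition oracle on random cases", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(30:200, 1)
    L <- sample(2:30, 1)
    s <- rnorm(n)
    tpl <- rnorm(L)
    expect_lt(max(abs(compute_ncc(s, tpl, fs = 1)$values - ncc_oracle(s, tpl))),
              1e-12)
  }
})

test_that("NCC is invariant to positive affine transforms of the signal", {
  set.seed(12)
  s <- rnorm(300)
  tpl <- rnorm(20)
  base <- compute_ncc(s, tpl, fs = 1)$values
  shifted <- compute_ncc(2.5 * s + 7, tpl, fs = 1)$values
  expect_lt(max(abs(base - shifted)), 1e-9)
  expect_true(all(abs(base) <= 1 + 1e-9))
})

test_that("NCC is symmetric in window and template at a fixed lag", {
  set.seed(13)
  a <- rnorm(15)
  b <- rnorm(15)
  expect_equal(compute_ncc(a, b, fs = 1)$values,
               compute_ncc(b, a, fs = 1)$values, tolerance = 1e-12)
})

test_that("constant signal windows give NCC = 0, never NaN", {
  s <- c(rep(2, 10), 1, 3, 2, 1)
  tpl <- c(1, 3, 2)
  v <- compute_ncc(s, tpl, fs = 1)$values
  expect_false(any(is.na(v)))
  expect_identical(v[1], 0)
})

test_that("template preconditions are enforced", {
  rec <- signal_record(rep(0, 100), rnorm(100), fs = 100)
  expect_error(select_template(rec, c(0, 0.2)), class = "scg_degenerate_error")
  expect_error(select_template(rec, c(0.5, 2)), class = "scg_range_error")
  expect_error(compute_ncc(rnorm(5), rnorm(10), fs = 1),
               class = "scg_length_error")
})

test_that("select_template recovers the generator's systolic peak", {
  synth <- generate_record(synth_config(duration_s = 30, snr_db = Inf,
                                        rr_jitter_sd_ms = 0, rsa_depth_ms = 0,
                                        resp_am_depth = 0, seed = 2))
  pre <- preprocess_record(synth$record)
  tb <- synth$truth_r$times_s[5]
  rr <- 60 / synth$config$mean_hr_bpm
  tpl1 <- select_template(pre, c(tb, tb + 0.9 * rr), case_label = 1)
  peak_t <- (tpl1$start_index + tpl1$systolic_peak_offset) / pre$fs
  expect_lt(abs(peak_t - synth$truth_sys_peak$times_s[5]), 0.005)
  # case 2: systolic complex only -> shorter template, same peak semantics
  tpl2 <- select_template(pre, c(tb, tb + 0.25), case_label = 2)
  expect_lt(length(tpl2$samples), length(tpl1$samples))
  peak_t2 <- (tpl2$start_index + tpl2$systolic_peak_offset) / pre$fs
  expect_lt(abs(peak_t2 - synth$truth_sys_peak$times_s[5]), 0.005)
})

test_that("find_ncc_peaks applies prominence and greedy minimum distance", {
  vals <- c(0, 0.9, 0, 0.8, 0)
  ncc <- structure(list(values = vals, lag_zero_time_s = 0, fs = 1000,
                        peak_lags = NULL, min_prominence = NA_real_,
                        min_distance_s = NA_real_), class = "scg_ncc")
  both <- find_ncc_peaks(ncc, min_prominence = 0.5, min_distance_s = 0.0005)
  expect_identical(both$peak_lags, c(1L, 3L))
  one <- find_ncc_peaks(ncc, min_prominence = 0.5, min_distance_s = 0.004)
  expect_identical(one$peak_lags, 1L)
  none <- find_ncc_peaks(
    structure(list(values = as.numeric(1:10), lag_zero_time_s = 0, fs = 1000),
              class = "scg_ncc"), 0.1, 0.001)
  expect_length(none$peak_lags, 0)
})

test_that("peak prominences match the brute-force oracle on random series", {
  set.seed(99)
  for (i in 1:10) {
    x <- cumsum(rnorm(120))
    or <- prominence_oracle(x)
    got <- scgbeat:::peak_prominences(x, or$peaks)
    expect_equal(got, or$prominence, tolerance = 1e-12)
    # selection with a threshold keeps exactly the oracle-qualified peaks
    keep <- or$peaks[or$prominence >= 0.8]
    expect_identical(scgbeat:::select_peaks(x, min_prominence = 0.8,
                                            min_distance = 1), sort(keep))
  }
})

test_that("beats_from_peaks adds the systolic offset; IBIs are offset-free", {
  ncc <- structure(list(values = numeric(0), lag_zero_time_s = 0, fs = 1000,
                        peak_lags = c(100L, 1100L)), class = "scg_ncc")
  beats <- beats_from_peaks(ncc, 50)
  expect_equal(beats$times_s, c(0.150, 1.150))
  expect_identical(beats$label, "NCC")
  expect_equal(diff(beats$times_s), diff((ncc$peak_lags) / 1000))
  empty <- structure(list(values = numeric(0), lag_zero_time_s = 0, fs = 1000,
                          peak_lags = integer(0)), class = "scg_ncc")
  expect_length(beats_from_peaks(empty, 50)$times_s, 0)
})

test_that("suggest_template is deterministic and flags pure noise", {
  synth <- quick_synth(duration_s = 30, snr_db = 30, seed = 21)
  pre <- preprocess_record(synth$record)
  rp <- detect_r_peaks(pre$ecg, pre$fs)
  t1 <- suggest_template(pre, rp$peaks, case_label = 1)
  t2 <- suggest_template(pre, rp$peaks, case_label = 1)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$start_index, t2$start_index)
  expect_false(t1$low_confidence)
  # pure noise: all candidate medians low -> low-confidence warning
  set.seed(8)
  noise <- signal_record(rnorm(20000), rnorm(20000), fs = 1000)
  fake_r <- beat_annotations(seq(0.5, 18.5, by = 1), "R")
  expect_warning(tn <- suggest_template(noise, fake_r, case_label = 1,
                                        min_prominence = 0.3),
                 "confidence")
  expect_true(tn$low_confidence)
  expect_error(suggest_template(pre, beat_annotations(c(1, 2, 3)), 1),
               class = "scg_insufficient_data_error")
})
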