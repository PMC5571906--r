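test_that("gap rule splits retention times as expected", {
  peaks <- random_peak_rows(3, rt = c(5.00, 5.03, 5.90))
  cl <- cluster_rt_ranges(peaks, rt_tol = 0.1)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$member_peaks$rt_min, c(5.00, 5.03))
  expect_equal(cl[[2]]$member_peaks$rt_min, 5.90)
  expect_length(cluster_rt_ranges(peaks[0, ], rt_tol = 0.1), 0L)
  peaks$method_id <- c("m1", "m1", "m2")
  expect_error(cluster_rt_ranges(peaks, 0.1), "method")
})

test_that("clustering equals the single-linkage transitive-closure oracle", {
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    peaks <- random_peak_rows(n, rt = round(runif(n, 0, 20), 3))
    tol <- sample(c(0.05, 0.1, 0.3), 1)
    cl <- cluster_rt_ranges(peaks, rt_tol = tol)
    oracle <- oracle_single_linkage(peaks$rt_min, tol)
    expect_equal(length(cl), length(unique(oracle)))
    got <- lapply(cl, function(c) sort(c$member_peaks$rt_min))
    want <- lapply(split(peaks$rt_min, oracle), sort)
    expect_equal(got, unname(want[order(vapply(want, min, 0))]),
                 ignore_attr = TRUE)
  }
})

test_that("clusters partition the input and satisfy the invariants", {
  set.seed(7)
  peaks <- random_peak_rows(120, rt = round(runif(120, 0, 15), 3))
  cl <- cluster_rt_ranges(peaks, rt_tol = 0.05)
  expect_equal(sum(vapply(cl, function(c) nrow(c$member_peaks), 0L)),
               nrow(peaks))
  for (c in cl) {
    expect_true(c$rt_lo <= c$rt_center && c$rt_center <= c$rt_hi)
    expect_true(all(c$member_peaks$rt_min >= c$rt_lo &
                      c$member_peaks$rt_min <= c$rt_hi))
    expect_equal(c$n_samples_present,
                 length(unique(c$member_peaks$sample_id)))
    expect_true(all(diff(sort(c$member_peaks$rt_min)) <= 0.05 + 1e-12))
  }
  centers <- vapply(cl, `[[`, 0, "rt_center")
  expect_true(all(diff(centers) > 0))
})

test_that("same-sample surplus peaks leave at most one peak per sample per cluster", {
  peaks <- random_peak_rows(6, rt = c(5.00, 5.02, 5.04, 5.30, 5.32, 9))
  peaks$sample_id <- c("s1", "s1", "s2", "s1", "s2", "s3")
  cl <- cluster_rt_ranges(peaks, rt_tol = 0.1)
  for (c in cl) {
    expect_false(any(duplicated(c$member_peaks$sample_id)))
  }
  expect_equal(sum(vapply(cl, function(c) nrow(c$member_peaks), 0L)), 6L)
})

test_that("occurrence filter applies the at-least-half rule with a ceiling", {
  mk <- function(n_samples) {
    peaks <- random_peak_rows(n_samples, rt = rep(5, n_samples) +
                                (1:n_samples) * 1e-4)
    cluster_rt_ranges(peaks, rt_tol = 0.1)
  }
  cl6 <- mk(6)   # present in 6 samples
  expect_length(occurrence_filter(cl6, 12, 0.5), 1L)
  cl5 <- mk(5)
  expect_length(occurrence_filter(cl5, 12, 0.5), 0L)
  expect_length(occurrence_filter(mk(12), 12, 1.0), 1L)
  expect_length(occurrence_filter(mk(11), 12, 1.0), 0L)
  # odd totals round up: 5 of 9 kept, 4 of 9 not
  expect_length(occurrence_filter(mk(5), 9, 0.5), 1L)
  expect_length(occurrence_filter(mk(4), 9, 0.5), 0L)
  expect_error(occurrence_filter(cl6, 0), "n_samples_total")
  # monotonicity: raising min_frac never increases the retained count
  set.seed(31)
  peaks <- random_peak_rows(80, rt = round(runif(80, 0, 10), 2))
  peaks$sample_id <- sample(sprintf("s%d", 1:12), 80, replace = TRUE)
  cl <- cluster_rt_ranges(peaks, rt_tol = 0.2)
  counts <- vapply(seq(0.1, 1, by = 0.1), function(f) {
    length(occurrence_filter(cl, 12, f))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("blank filter keeps higher-in-animal clusters and reports removals", {
  mk_cluster <- function(rt, area, n = 3) {
    peaks <- random_peak_rows(n, rt = rep(rt, n) + (1:n) * 1e-4)
    peaks$area <- rep(area, n)
    cluster_rt_ranges(peaks, rt_tol = 0.1)[[1]]
  }
  animal <- list(mk_cluster(5, 1000), mk_cluster(8, 300))
  blank <- list(mk_cluster(5.01, 400), mk_cluster(8.02, 400))
  out <- blank_filter(animal, blank, rt_tol = 0.05)
  expect_length(out$kept, 1L)
  expect_equal(out$kept[[1]]$rt_center, animal[[1]]$rt_center)
  expect_equal(nrow(out$removed), 1L)
  expect_equal(out$removed$blank_mean_area, 400)
  # no blank counterpart within tolerance -> retained
  out2 <- blank_filter(animal, list(mk_cluster(12, 1e6)), rt_tol = 0.05)
  expect_length(out2$kept, 2L)
})

test_that("blank correction separates contaminants from endogenous compounds on truth-labelled data", {
  specs <- lapply(default_method_specs(rt_jitter_sd = 0)["td_mix"],
                  function(s) { s$sensitivity <- 1; s })
  ds <- generate_dataset(methods = specs, seed = 21, blank_factor = 2,
                         blank_noise_rate = 0, spectrum_noise_sd = 0)
  prof <- build_method_profile(ds$peaks, rt_tol = 0.05)
  expect_equal(length(prof$compounds),
               length(ds$truth$animal_detectable$td_mix))
  expect_equal(prof$n_after_occurrence,
               length(ds$truth$detectable$td_mix))
  # removed clusters sit at contaminant retention times
  cmp <- ds$truth$panel$compounds
  exo <- cmp[cmp$compound_id %in%
               setdiff(ds$truth$detectable$td_mix,
                       ds$truth$animal_detectable$td_mix), ]
  exo_rt <- instrument_observed_rt(exo$true_rt_index, specs$td_mix)
  expect_equal(nrow(prof$removed_blank), nrow(exo))
  expect_true(all(vapply(prof$removed_blank$rt_center, function(rt) {
    min(abs(exo_rt - rt)) < 0.05
  }, TRUE)))
})
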