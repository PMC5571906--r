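test_that("noiseless single-compound config yields one identical peak per sample", {
  panel <- list(
    compounds = data.frame(compound_id = "cmpd_001", name = "only one",
                           true_rt_index = 5, boiling_point_c = 120,
                           origin_class = "potentially_endogenous",
                           mean_log_abundance = 13,
                           stringsAsFactors = FALSE),
    spectra = list(cmpd_001 = cbind(mz = c(43, 57, 71),
                                    intensity = c(999, 400, 120)))
  )
  spec <- method_spec("m1", sensitivity = 1, rt_jitter_sd = 0,
                      n_blanks = 0)
  ds <- generate_dataset(methods = list(spec), seed = 4, panel = panel,
                         spectrum_noise_sd = 0)
  expect_equal(nrow(ds$peaks), 12L)  # 6 animals x 2 replicates
  expect_equal(unname(table(ds$peaks$sample_id)), rep(1L, 12L),
               ignore_attr = TRUE)
  expect_equal(length(unique(ds$peaks$rt_min)), 1L)
})

test_that("identical seed and config reproduce the dataset byte-identically", {
  d1 <- generate_dataset(seed = 11)
  d2 <- generate_dataset(seed = 11)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$library, d2$library)
  d3 <- generate_dataset(seed = 12)
  expect_false(identical(d1$peaks, d3$peaks))
})

test_that("detectable fraction under a (0, 250) window equals the panel boiling-point fraction", {
  ds <- generate_dataset(seed = 1)
  cmp <- ds$truth$panel$compounds
  frac_bp <- mean(cmp$boiling_point_c < 250)
  frac_det <- length(ds$truth$detectable$mobile) / nrow(cmp)
  expect_equal(frac_det, frac_bp)
})

test_that("no peak of an out-of-window compound appears in a method's samples", {
  ds <- generate_dataset(seed = 2)
  cmp <- ds$truth$panel$compounds
  asg <- ds$truth$assignments
  for (m in names(ds$methods)) {
    win <- ds$methods[[m]]$volatility_window
    ids <- asg$truth_id[asg$method_id == m]
    ids <- ids[ids %in% cmp$compound_id]
    bp <- cmp$boiling_point_c[match(ids, cmp$compound_id)]
    expect_true(all(bp >= win[1] & bp <= win[2]), label = m)
  }
})

test_that("blanks contain only contaminant and noise peaks", {
  ds <- generate_dataset(seed = 3)
  cmp <- ds$truth$panel$compounds
  asg <- ds$truth$assignments
  blank_ids <- asg$truth_id[asg$is_blank]
  compound_ids <- blank_ids[blank_ids %in% cmp$compound_id]
  origin <- cmp$origin_class[match(compound_ids, cmp$compound_id)]
  expect_true(all(origin == "exogenous"))
  expect_true(all(grepl("^noise_", setdiff(blank_ids, cmp$compound_id))))
  # and every non-blank peak traces to exactly one panel compound
  animal_ids <- asg$truth_id[!asg$is_blank]
  expect_true(all(animal_ids %in% cmp$compound_id))
})

test_that("zero-jitter elution order is preserved across any two instrument maps", {
  spec_a <- method_spec("a", rt_map = c(intercept = 0.5, slope = 0.4,
                                        quad = 0.002), rt_jitter_sd = 0)
  spec_b <- method_spec("b", rt_map = c(intercept = 3, slope = 1.1,
                                        quad = 0), rt_jitter_sd = 0)
  t <- sort(runif(20, 1, 20))
  rt_a <- instrument_observed_rt(t, spec_a)
  rt_b <- instrument_observed_rt(t, spec_b)
  expect_true(all(diff(rt_a) > 0))
  expect_true(all(diff(rt_b) > 0))
  expect_equal(cor(rt_a, rt_b, method = "spearman"), 1)
  # identity map fixed point
  ident <- method_spec("id", rt_map = c(intercept = 0, slope = 1, quad = 0),
                       rt_jitter_sd = 0)
  expect_equal(instrument_observed_rt(5.0, ident), 5.0)
})

test_that("degenerate configurations are rejected", {
  bad <- method_spec("bad", rt_map = c(intercept = 1, slope = 0.1,
                                       quad = -0.1))
  expect_error(generate_dataset(methods = list(bad), seed = 1),
               "strictly increasing")
  empty_panel <- list(compounds = data.frame(), spectra = list())
  expect_error(generate_dataset(seed = 1, panel = empty_panel), "empty")
  expect_error(method_spec("m", sensitivity = 0))
})

test_that("detection probability increases with abundance and saturates at sensitivity 1", {
  m <- seq(8, 18, by = 0.5)
  p <- vocompare:::detection_prob(m, 0.4, panel_mean = 13)
  expect_true(all(diff(p) > 0))
  expect_equal(vocompare:::detection_prob(13, 0.4, 13), 0.4)
  expect_equal(vocompare:::detection_prob(m, 1, 13), rep(1, length(m)))
})
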