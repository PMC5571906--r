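test_that("match factor hits its self-match, disjoint and hand-computed values", {
  s <- cbind(mz = c(91, 92), intensity = c(999, 600))
  expect_equal(spectral_match_score(s, s), 999L)
  t <- cbind(mz = c(41, 43, 55), intensity = c(999, 500, 100))
  expect_equal(spectral_match_score(s, t), 0L)
  ref <- cbind(mz = 91, intensity = 999)
  expect_equal(spectral_match_score(s, ref), oracle_match_score(s, ref))
  # a second closed-form case with partial overlap
  q2 <- cbind(mz = c(43, 57, 71), intensity = c(999, 420, 100))
  r2 <- cbind(mz = c(43, 71, 85), intensity = c(800, 300, 250))
  expect_equal(spectral_match_score(q2, r2), oracle_match_score(q2, r2))
  expect_error(spectral_match_score(s, s[0, , drop = FALSE]), "empty")
})

test_that("match factor is bounded, symmetric and monotone in shared intensity", {
  set.seed(17)
  for (i in 1:20) {
    a <- cbind(mz = sort(sample(30:300, 8)), intensity = runif(8, 1, 999))
    b <- cbind(mz = sort(sample(30:300, 8)), intensity = runif(8, 1, 999))
    s_ab <- spectral_match_score(a, b)
    expect_true(s_ab >= 0 && s_ab <= 999)
    expect_equal(s_ab, spectral_match_score(b, a))
  }
  # zeroing a shared stick never raises the score
  a <- cbind(mz = c(50, 60, 70, 80), intensity = c(999, 500, 400, 300))
  b <- cbind(mz = c(50, 60, 70, 95), intensity = c(900, 450, 350, 200))
  full <- spectral_match_score(a, b)
  a2 <- a; a2[2, "intensity"] <- 1e-9
  expect_true(spectral_match_score(a2, b) <= full)
})

test_that("volatility classification is strict at the 250 degC boundary", {
  expect_equal(classify_volatility(95), "volatile")
  expect_equal(classify_volatility(209), "volatile")
  expect_equal(classify_volatility(250), "semi_or_nonvolatile")
  expect_equal(classify_volatility(310), "semi_or_nonvolatile")
  expect_error(classify_volatility(NA_real_), "finite")
})

test_that("origin classification resolves aliases and missing names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,boiling_point_c,origin_class",
               "Toluene,111,exo",
               "Nonanal,191,pot metab"), path)
  meta <- read_compound_metadata(path)
  expect_equal(classify_origin("Toluene", meta), "exogenous")
  expect_equal(classify_origin("nonanal", meta), "potentially_metabolized")
  expect_equal(classify_origin("Zyzzyvanol", meta), "unclassified")
})

test_that("majority rule names a cluster only on a strict majority of member samples", {
  lib <- list(
    list(name = "target", cas = NA, boiling_point_c = 120,
         spectrum = cbind(mz = c(43, 57, 71, 85),
                          intensity = c(999, 500, 250, 100))),
    list(name = "decoy", cas = NA, boiling_point_c = 300,
         spectrum = cbind(mz = c(44, 58, 72, 86),
                          intensity = c(999, 500, 250, 100)))
  )
  mk_cluster <- function(specs) {
    peaks <- random_peak_rows(length(specs), rt = rep(5, length(specs)) +
                                seq_along(specs) * 1e-4)
    peaks$spectrum <- vapply(specs, encode_spectrum, "")
    cluster_rt_ranges(peaks, rt_tol = 0.1)[[1]]
  }
  target_like <- lib[[1]]$spectrum
  decoy_like <- lib[[2]]$spectrum
  # 11 of 12 member samples vote for the target
  ann <- annotate_cluster(mk_cluster(c(rep(list(target_like), 11),
                                       list(decoy_like))), lib)
  expect_equal(ann$name, "target")
  expect_true(ann$match_score > 700)
  expect_equal(ann$volatility, "volatile")  # bp from the library entry
  # an even split is not a strict majority
  ann2 <- annotate_cluster(mk_cluster(c(rep(list(target_like), 6),
                                        rep(list(decoy_like), 6))), lib)
  expect_true(is.na(ann2$name))
  expect_true(is.na(ann2$match_score))
  expect_equal(ann2$volatility, "unknown")
  # raising min_score never increases the number of named clusters
  noisy <- lapply(1:12, function(i) {
    s <- target_like
    s[, "intensity"] <- s[, "intensity"] * exp(rnorm(4, 0, 0.5))
    s
  })
  cl <- mk_cluster(noisy)
  named <- vapply(c(0, 300, 700, 900, 990), function(ms) {
    !is.na(annotate_cluster(cl, lib, min_score = ms)$name)
  }, TRUE)
  expect_true(all(diff(named) <= 0))
})

test_that("clusters with their true compound in the library are named correctly", {
  correct <- 0L; total <- 0L
  for (seed in 1:3) {
    specs <- default_method_specs()["td_mix"]
    ds <- generate_dataset(methods = specs, seed = seed,
                           library_coverage = 1)
    prof <- build_method_profile(ds$peaks)
    meta_path <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(ds$metadata, meta_path, row.names = FALSE)
    ann <- annotate_profile(prof, ds$library,
                            read_compound_metadata(meta_path))
    cmp <- ds$truth$panel$compounds
    for (a in ann$compounds) {
      rt_true <- instrument_observed_rt(cmp$true_rt_index, specs$td_mix,
                                        jitter = FALSE)
      truth_name <- cmp$name[which.min(abs(rt_true - a$cluster$rt_center))]
      total <- total + 1L
      if (!is.na(a$name) && a$name == truth_name) correct <- correct + 1L
    }
  }
  expect_gt(correct / total, 0.95)
})
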