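make_profiles_from_panel <- function(n = 20, seed = 1) {
  specs <- list(
    a = method_spec("a", sensitivity = 1, rt_jitter_sd = 0, n_blanks = 0,
                    rt_map = c(intercept = 0.6, slope = 0.45, quad = 0.001)),
    b = method_spec("b", sensitivity = 1, rt_jitter_sd = 0, n_blanks = 0,
                    rt_map = c(intercept = 2, slope = 0.75, quad = 0))
  )
  ds <- generate_dataset(methods = specs, seed = seed, n_compounds = n,
                         spectrum_noise_sd = 0)
  list(
    a = build_method_profile(ds$peaks[ds$peaks$method_id == "a", ]),
    b = build_method_profile(ds$peaks[ds$peaks$method_id == "b", ]),
    ds = ds
  )
}

test_that("same-panel zero-jitter profiles match completely and in order", {
  p <- make_profiles_from_panel(20, seed = 8)
  m <- match_across_methods(p$a, p$b)
  expect_equal(nrow(m$pairs), 20L)
  expect_length(m$unique_a, 0L)
  expect_length(m$unique_b, 0L)
  expect_true(all(diff(m$pairs$rt_a) > 0))
  expect_true(all(diff(m$pairs$rt_b) > 0))
  expect_false(any(duplicated(m$pairs$index_a)))
  expect_false(any(duplicated(m$pairs$index_b)))
})

test_that("profiles without shared ions yield no pairs", {
  p <- make_profiles_from_panel(10, seed = 9)
  shifted <- p$b
  for (i in seq_along(shifted$compounds)) {
    sp <- shifted$compounds[[i]]$consensus_spectrum
    sp[, "mz"] <- sp[, "mz"] + 400  # move all ions out of range
    shifted$compounds[[i]]$consensus_spectrum <- sp
  }
  m <- match_across_methods(p$a, shifted)
  expect_equal(nrow(m$pairs), 0L)
  expect_length(m$unique_a, 10L)
  expect_length(m$unique_b, 10L)
})

test_that("subset sharing in matching elution order pairs exactly that subset", {
  p <- make_profiles_from_panel(5, seed = 10)
  # keep shared ions only for compounds 2 and 4 on side B
  b <- p$b
  for (i in c(1, 3, 5)) {
    sp <- b$compounds[[i]]$consensus_spectrum
    sp[, "mz"] <- sp[, "mz"] + 400
    b$compounds[[i]]$consensus_spectrum <- sp
  }
  m <- match_across_methods(p$a, b)
  expect_equal(m$pairs$index_a, c(2L, 4L))
  expect_equal(m$pairs$index_b, c(2L, 4L))
})

test_that("DP matching cardinality equals exhaustive search on small instances", {
  set.seed(55)
  for (rep in 1:30) {
    m <- sample(4:12, 1)
    rt_a <- runif(m, 0, 10)
    rt_b <- runif(m, 0, 10)
    sel <- vocompare:::chain_matching(rt_a, rt_b, runif(m))
    expect_equal(length(sel), oracle_max_chain(rt_a, rt_b))
    expect_true(all(diff(rt_a[sel][order(rt_a[sel])]) > 0))
    o <- order(rt_a[sel])
    expect_true(all(diff(rt_b[sel][o]) > 0))
  }
})

test_that("order preservation holds on random candidate structures", {
  set.seed(77)
  for (rep in 1:10) {
    p <- make_profiles_from_panel(sample(8:25, 1), seed = 100 + rep)
    m <- match_across_methods(p$a, p$b)
    if (nrow(m$pairs) >= 2) {
      o <- order(m$pairs$rt_a)
      expect_true(all(diff(m$pairs$rt_b[o]) > 0))
    }
    expect_equal(nrow(m$pairs) + length(m$unique_a), m$n_a)
    expect_equal(nrow(m$pairs) + length(m$unique_b), m$n_b)
  }
})

test_that("n_diagnostic above the ion shortlist is a configuration error", {
  p <- make_profiles_from_panel(5, seed = 11)
  expect_error(match_across_methods(p$a, p$b, n_diagnostic = 9, k = 8),
               "exceeds")
})

test_that("rank correlation handles monotone, antitone and degenerate cases", {
  rt <- data.frame(rt_a = 1:10, rt_b = (1:10)^2)
  expect_equal(rt_rank_correlation(rt)$rho, 1)
  rt$rt_b <- rev(rt$rt_b)
  expect_equal(rt_rank_correlation(rt)$rho, -1)
  expect_error(rt_rank_correlation(rt[1:2, ]), "3")
  r <- spearman_correlation(1:5, rep(2, 5))
  expect_equal(r$status, "degenerate")
  expect_true(is.na(r$rho))
})

test_that("exact permutation p-values agree with cor.test for tie-free small n", {
  set.seed(5)
  for (n in c(4, 6, 8, 9)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearman_correlation(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$method, "exact")
  }
})

test_that("area correlations are near zero under independent response factors", {
  set.seed(202)
  rhos <- replicate(60, {
    n <- 15
    spearman_correlation(runif(n), runif(n))$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("retrieval fractions follow the count arithmetic", {
  prof_names <- c(sprintf("cmpd %02d", 1:22))
  expect_equal(adsorbent_retrieval(prof_names, prof_names)$fraction, 1)
  r <- adsorbent_retrieval(prof_names, prof_names[1:3])
  expect_equal(r$n_searched, 22L)
  expect_equal(r$n_retrieved, 3L)
  expect_equal(r$fraction, 3 / 22, tolerance = 1e-12)
  expect_equal(adsorbent_retrieval(sprintf("x%d", 1:6),
                                   prof_names)$fraction, 0)
  expect_error(adsorbent_retrieval(character(0), prof_names), "empty")
})

test_that("zero-jitter matching has perfect recall and precision against truth", {
  p <- make_profiles_from_panel(25, seed = 33)
  m <- match_across_methods(p$a, p$b)
  cmp <- p$ds$truth$panel$compounds
  # with identical panels both profiles hold all compounds in panel order
  expect_equal(nrow(m$pairs), nrow(cmp))
  expect_equal(m$pairs$index_a, m$pairs$index_b)
})
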