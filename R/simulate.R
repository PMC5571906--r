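## Synthetic multi-method GC-MS study generator
## --------------------------------------------
## Emulates the design of a marmoset body-odor method comparison: a latent
## panel of compounds with boiling points, elution coordinates, log-scale
## abundances and EI stick spectra is observed through several sampling
## methods, each with its own sensitivity, volatility coverage window,
## monotone retention-time mapping and noise levels; procedural blanks carry
## the exogenous (contaminant) compounds plus spurious noise peaks.

#' Describe one sampling method / instrument
#'
#' @param method_id Method label, e.g. `"td_mix"`.
#' @param sensitivity Detection-probability scale in (0, 1]. A compound of
#'   panel-average abundance is detected per sample with this probability;
#'   detection probability rises logistically with mean log abundance and
#'   equals 1 everywhere when `sensitivity = 1`.
#' @param volatility_window `c(bp_min_c, bp_max_c)`: boiling-point range
#'   (degC) the method can capture. Compounds outside never appear in its
#'   samples.
#' @param rt_map Named numeric `c(intercept, slope, quad)`: observed RT
#'   (min) `= intercept + slope * t + quad * t^2` of the latent elution
#'   coordinate `t`; must be strictly increasing over the panel range.
#' @param rt_jitter_sd RT jitter SD, min.
#' @param area_noise_sd Per-observation log-area noise SD.
#' @param n_animals,n_replicates_per_animal Sample design (default 6 animals
#'   x 2 replicates = 12 samples).
#' @param n_blanks Procedural blanks for this method.
#' @return An object of class `"method_spec"`.
#' @export
method_spec <- function(method_id,
                        sensitivity = 1,
                        volatility_window = c(0, 400),
                        rt_map = c(intercept = 1, slope = 0.8, quad = 0),
                        rt_jitter_sd = 0,
                        area_noise_sd = 0.5,
                        n_animals = 6,
                        n_replicates_per_animal = 2,
                        n_blanks = 3) {
  stopifnot(is.character(method_id), length(method_id) == 1L,
            sensitivity > 0, sensitivity <= 1,
            length(volatility_window) == 2L,
            volatility_window[1L] < volatility_window[2L],
            length(rt_map) == 3L,
            rt_jitter_sd >= 0, area_noise_sd >= 0,
            n_animals >= 1, n_replicates_per_animal >= 1, n_blanks >= 0)
  names(rt_map) <- c("intercept", "slope", "quad")
  structure(list(method_id = method_id, sensitivity = sensitivity,
                 volatility_window = volatility_window, rt_map = rt_map,
                 rt_jitter_sd = rt_jitter_sd, area_noise_sd = area_noise_sd,
                 n_animals = as.integer(n_animals),
                 n_replicates_per_animal = as.integer(n_replicates_per_animal),
                 n_blanks = as.integer(n_blanks)),
            class = "method_spec")
}

## derivative of the quadratic map is linear in t: positivity at the range
## endpoints implies positivity throughout
check_rt_map <- function(spec, rt_index_range) {
  d <- spec$rt_map[["slope"]] + 2 * spec$rt_map[["quad"]] * rt_index_range
  if (any(d <= 0)) {
    stop("rt_map of method '", spec$method_id,
         "' is not strictly increasing over the elution-coordinate range",
         call. = FALSE)
  }
  invisible(spec)
}

#' Map a latent elution coordinate to an observed retention time
#'
#' Applies the method's affine-plus-curvature RT map and, if the spec has
#' `rt_jitter_sd > 0`, adds Gaussian jitter drawn from the current RNG
#' state. With zero jitter the map is strictly increasing, so elution order
#' is identical under any two method specs.
#'
#' @param true_rt_index Latent elution coordinate(s).
#' @param spec A [method_spec()].
#' @param jitter Set `FALSE` to suppress jitter regardless of the spec.
#' @return Observed retention time(s) in minutes.
#' @export
instrument_observed_rt <- function(true_rt_index, spec, jitter = TRUE) {
  m <- spec$rt_map
  rt <- m[["intercept"]] + m[["slope"]] * true_rt_index +
    m[["quad"]] * true_rt_index^2
  if (jitter && spec$rt_jitter_sd > 0) {
    rt <- rt + stats::rnorm(length(rt), 0, spec$rt_jitter_sd)
  }
  rt
}

#' Default method roster of the emulated study
#'
#' Five methods: cotton swabs (semi/non-volatile-biased, moderate
#' sensitivity), a mobile GC-MS (volatile-only window, low sensitivity,
#' fast column), a mixed-bed thermal-desorption tube (broadest coverage,
#' highest sensitivity), and single-adsorbent Tenax TA and XAD-4 tubes
#' (XAD-4 with 5 animals, i.e. 10 samples). All follow the 2-replicates-
#' per-animal design with 3 blanks per method.
#'
#' @param rt_jitter_sd RT jitter applied to every method (default 0.01 min).
#' @return Named list of [method_spec()] objects.
#' @export
default_method_specs <- function(rt_jitter_sd = 0.01) {
  specs <- list(
    method_spec("cotton", sensitivity = 0.75,
                volatility_window = c(150, 400),
                rt_map = c(intercept = 0.5, slope = 1.3, quad = 0.002),
                rt_jitter_sd = rt_jitter_sd),
    method_spec("mobile", sensitivity = 0.35,
                volatility_window = c(0, 250),
                rt_map = c(intercept = 0.6, slope = 0.45, quad = 0.001),
                rt_jitter_sd = rt_jitter_sd),
    method_spec("td_mix", sensitivity = 0.95,
                volatility_window = c(0, 400),
                rt_map = c(intercept = 2, slope = 0.75, quad = 0.001),
                rt_jitter_sd = rt_jitter_sd),
    method_spec("td_tenax", sensitivity = 0.9,
                volatility_window = c(0, 350),
                rt_map = c(intercept = 1.5, slope = 0.8, quad = 0),
                rt_jitter_sd = rt_jitter_sd),
    method_spec("td_xad4", sensitivity = 0.85,
                volatility_window = c(60, 380),
                rt_map = c(intercept = 1, slope = 0.9, quad = 0.0015),
                rt_jitter_sd = rt_jitter_sd, n_animals = 5)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "method_id"))
}

## deterministic sub-seed derivation: a counter-based split of the master
## seed so per-method / per-stage streams are independent yet reproducible;
## intermediate products stay < 2^53 so the arithmetic is exact in doubles
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                counter * 2246822519) %% 2147483647)
}

random_spectrum <- function(n_min = 6L, n_max = 25L) {
  n <- sample.int(n_max - n_min + 1L, 1L) + n_min - 1L
  mz <- sort(sample(30:300, n))
  intensity <- c(999, pmax(5, round(999 * stats::runif(n - 1L)^2)))
  intensity <- intensity[sample.int(n)]
  intensity[which.max(intensity)] <- 999
  cbind(mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' Simulate a latent compound panel
#'
#' @param n_compounds Panel size (default 60).
#' @param bp_range Boiling-point range, degC (default 80--400, spanning both
#'   sides of the 250 degC volatility threshold).
#' @param rt_index_range Latent elution-coordinate range.
#' @param min_rt_gap Minimum spacing between consecutive elution
#'   coordinates (default 0.12). Mirrors finite chromatographic peak
#'   capacity: distinct compounds that co-elute are not separable by any
#'   peak-table method, so the panel keeps compounds resolvable under every
#'   default instrument map.
#' @param origin_probs Category probabilities for
#'   exogenous / potentially endogenous / potentially metabolized /
#'   unclassified (defaults 0.12 / 0.34 / 0.50 / 0.04, the composition
#'   reported for curated primate body-odor compound sets).
#' @param mean_log_area,sd_log_area Natural-log abundance distribution of
#'   the panel (defaults give peak areas of roughly 1e4--1e8 counts).
#' @return List with `compounds` (data.frame: `compound_id`, `name`,
#'   `true_rt_index`, `boiling_point_c`, `origin_class`,
#'   `mean_log_abundance`) and `spectra` (named list of stick matrices).
#' @export
simulate_compound_panel <- function(n_compounds = 60,
                                    bp_range = c(80, 400),
                                    rt_index_range = c(1, 20),
                                    origin_probs = c(
                                      exogenous = 0.12,
                                      potentially_endogenous = 0.34,
                                      potentially_metabolized = 0.50,
                                      unclassified = 0.04),
                                    mean_log_area = 13,
                                    sd_log_area = 2,
                                    min_rt_gap = 0.12) {
  stopifnot(n_compounds >= 1)
  span_needed <- (n_compounds - 1L) * min_rt_gap
  if (diff(rt_index_range) <= span_needed) {
    stop("rt_index_range too narrow for ", n_compounds,
         " compounds at min_rt_gap ", min_rt_gap, call. = FALSE)
  }
  # uniform order statistics on the shrunken range + cumulative gap offsets
  # = uniform conditional on the minimum spacing
  base <- sort(stats::runif(n_compounds, rt_index_range[1L],
                            rt_index_range[2L] - span_needed))
  ids <- sprintf("cmpd_%03d", seq_len(n_compounds))
  compounds <- data.frame(
    compound_id = ids,
    name = sprintf("synthetic compound %03d", seq_len(n_compounds)),
    true_rt_index = base + min_rt_gap * (seq_len(n_compounds) - 1L),
    boiling_point_c = stats::runif(n_compounds, bp_range[1L], bp_range[2L]),
    origin_class = sample(names(origin_probs), n_compounds, replace = TRUE,
                          prob = origin_probs),
    mean_log_abundance = stats::rnorm(n_compounds, mean_log_area,
                                      sd_log_area),
    stringsAsFactors = FALSE
  )
  spectra <- stats::setNames(
    lapply(seq_len(n_compounds), function(i) random_spectrum()), ids)
  list(compounds = compounds, spectra = spectra)
}

## p(detect | mean log abundance m): logistic with intercept qlogis(s), so
## a panel-average compound is caught with probability = sensitivity and
## sensitivity 1 means certain detection (qlogis(1) = Inf)
detection_prob <- function(mean_log_abundance, sensitivity, panel_mean,
                           tau = 1.5) {
  stats::plogis(stats::qlogis(sensitivity) +
                  (mean_log_abundance - panel_mean) / tau)
}

#' Generate a complete synthetic multi-method dataset
#'
#' Draws a latent compound panel, observes it through each method of
#' `methods` (6 animals x 2 replicates by default, method-specific blanks),
#' and assembles the peak tables, a spectral library, the compound metadata
#' table and the generating truth. Identical `seed` + configuration gives
#' byte-identical output.
#'
#' Animal samples contain every panel compound whose boiling point falls in
#' the method's volatility window, subject to the logistic detection model;
#' per-sample areas are log-normal around the compound's mean log abundance
#' plus a per-animal random effect. Blanks contain the exogenous
#' (contaminant) compounds at `blank_factor` times the sample-level mean
#' area, plus Poisson-distributed spurious noise peaks — so the blank filter
#' downstream has true positives and true negatives.
#'
#' @param methods List of [method_spec()]s (default [default_method_specs()]).
#' @param seed Integer master seed; all randomness derives from it via a
#'   counter-based split per stage and method.
#' @param panel Optional pre-built panel from [simulate_compound_panel()];
#'   built under the derived panel seed when `NULL`.
#' @param n_compounds Panel size when `panel` is `NULL`.
#' @param blank_factor Contaminant enrichment of blanks relative to animal
#'   samples (default 2).
#' @param blank_noise_rate Poisson mean of spurious peaks per blank
#'   (default 2).
#' @param library_coverage Fraction of panel compounds present in the
#'   spectral library (default 0.9); 10 decoy entries are always added.
#' @param animal_sd SD of the per-animal log-abundance random effect.
#' @param spectrum_noise_sd Multiplicative log-normal noise on observed
#'   stick intensities (default 0.1).
#' @return An object of class `"vc_dataset"`: a list with `peaks` (one
#'   peak-table data.frame covering all methods and blanks), `library`,
#'   `metadata` (data.frame), `methods`, and `truth` (panel, per-method
#'   `detectable` and `animal_detectable` compound-id sets, per-peak
#'   `assignments` with a `truth_id` column, animal effects).
#' @export
generate_dataset <- function(methods = default_method_specs(),
                             seed = 1L,
                             panel = NULL,
                             n_compounds = 60,
                             blank_factor = 2,
                             blank_noise_rate = 2,
                             library_coverage = 0.9,
                             animal_sd = 0.3,
                             spectrum_noise_sd = 0.1) {
  if (inherits(methods, "method_spec")) methods <- list(methods)
  stopifnot(length(methods) >= 1L)
  rt_index_range <- c(1, 20)
  for (spec in methods) check_rt_map(spec, rt_index_range)

  set.seed(derive_seed(seed, 0))
  if (is.null(panel)) {
    panel <- simulate_compound_panel(n_compounds = n_compounds,
                                     rt_index_range = rt_index_range)
  }
  cmp <- panel$compounds
  if (nrow(cmp) < 1L) stop("empty compound panel", call. = FALSE)
  panel_mean <- mean(cmp$mean_log_abundance)
  max_animals <- max(vapply(methods, `[[`, 1L, "n_animals"))
  animal_ids <- sprintf("animal_%d", seq_len(max_animals))
  animal_effect <- stats::setNames(stats::rnorm(max_animals, 0, animal_sd),
                                   animal_ids)

  observe_spectrum <- function(spec_matrix) {
    if (spectrum_noise_sd > 0) {
      spec_matrix[, "intensity"] <- spec_matrix[, "intensity"] *
        exp(stats::rnorm(nrow(spec_matrix), 0, spectrum_noise_sd))
    }
    spec_matrix
  }

  detectable <- list(); animal_detectable <- list()
  rows <- list()
  for (mi in seq_along(methods)) {
    spec <- methods[[mi]]
    set.seed(derive_seed(seed, mi))
    in_window <- cmp$boiling_point_c >= spec$volatility_window[1L] &
      cmp$boiling_point_c <= spec$volatility_window[2L]
    detectable[[spec$method_id]] <- cmp$compound_id[in_window]
    animal_detectable[[spec$method_id]] <-
      cmp$compound_id[in_window & cmp$origin_class != "exogenous"]
    det_p <- detection_prob(cmp$mean_log_abundance, spec$sensitivity,
                            panel_mean)

    for (a in seq_len(spec$n_animals)) {
      for (r in seq_len(spec$n_replicates_per_animal)) {
        sid <- sprintf("%s_%s_r%d", spec$method_id, animal_ids[a], r)
        hit <- which(in_window & stats::runif(nrow(cmp)) < det_p)
        for (i in hit) {
          rows[[length(rows) + 1L]] <- list(
            sample_id = sid, animal_id = animal_ids[a],
            method_id = spec$method_id, is_blank = FALSE,
            rt_min = instrument_observed_rt(cmp$true_rt_index[i], spec),
            area = exp(cmp$mean_log_abundance[i] + animal_effect[a] +
                         stats::rnorm(1, 0, spec$area_noise_sd)),
            spectrum = encode_spectrum(
              observe_spectrum(panel$spectra[[cmp$compound_id[i]]])),
            truth_id = cmp$compound_id[i])
        }
      }
    }

    contaminant <- which(in_window & cmp$origin_class == "exogenous")
    rt_span <- range(instrument_observed_rt(rt_index_range, spec,
                                            jitter = FALSE))
    for (b in seq_len(spec$n_blanks)) {
      sid <- sprintf("%s_blank_%d", spec$method_id, b)
      for (i in contaminant) {
        rows[[length(rows) + 1L]] <- list(
          sample_id = sid, animal_id = "", method_id = spec$method_id,
          is_blank = TRUE,
          rt_min = instrument_observed_rt(cmp$true_rt_index[i], spec),
          area = blank_factor * exp(cmp$mean_log_abundance[i] +
                                      stats::rnorm(1, 0,
                                                   spec$area_noise_sd)),
          spectrum = encode_spectrum(
            observe_spectrum(panel$spectra[[cmp$compound_id[i]]])),
          truth_id = cmp$compound_id[i])
      }
      n_noise <- stats::rpois(1, blank_noise_rate)
      for (j in seq_len(n_noise)) {
        rows[[length(rows) + 1L]] <- list(
          sample_id = sid, animal_id = "", method_id = spec$method_id,
          is_blank = TRUE,
          rt_min = stats::runif(1, rt_span[1L], rt_span[2L]),
          area = exp(stats::rnorm(1, 11, 1)),
          spectrum = encode_spectrum(random_spectrum(3L, 8L)),
          truth_id = sprintf("noise_%s_b%d_%d", spec$method_id, b, j))
      }
    }
  }
  peaks <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(peaks)) {
    peaks <- data.frame(sample_id = character(), animal_id = character(),
                        method_id = character(), is_blank = logical(),
                        rt_min = numeric(), area = numeric(),
                        spectrum = character(), truth_id = character(),
                        stringsAsFactors = FALSE)
  }

  set.seed(derive_seed(seed, length(methods) + 1L))
  in_lib <- stats::runif(nrow(cmp)) < library_coverage
  library <- lapply(which(in_lib), function(i) {
    list(name = cmp$name[i],
         cas = pseudo_cas(i),
         boiling_point_c = cmp$boiling_point_c[i],
         spectrum = panel$spectra[[cmp$compound_id[i]]])
  })
  decoys <- lapply(seq_len(10L), function(k) {
    list(name = sprintf("decoy compound %02d", k), cas = NA_character_,
         boiling_point_c = stats::runif(1, 80, 400),
         spectrum = random_spectrum())
  })
  library <- c(library, decoys)

  metadata <- data.frame(
    compound_id = cmp$compound_id,
    name = cmp$name,
    cas = pseudo_cas(seq_len(nrow(cmp))),
    boiling_point_c = cmp$boiling_point_c,
    origin_class = cmp$origin_class,
    stringsAsFactors = FALSE
  )

  structure(list(
    peaks = peaks[, PEAK_COLUMNS],
    library = library,
    metadata = metadata,
    methods = methods,
    truth = list(panel = panel,
                 detectable = detectable,
                 animal_detectable = animal_detectable,
                 assignments = peaks,
                 animal_effect = animal_effect,
                 in_library = stats::setNames(in_lib, cmp$compound_id),
                 seed = seed)
  ), class = "vc_dataset")
}

pseudo_cas <- function(i) sprintf("%04d-%02d-%d", 1000 + i, i %% 90 + 10,
                                  i %% 10)

#' @export
print.vc_dataset <- function(x, ...) {
  cat("Synthetic GC-MS method-comparison dataset\n")
  cat(sprintf("  panel: %d compounds; methods: %s\n",
              nrow(x$truth$panel$compounds),
              paste(names(x$truth$detectable), collapse = ", ")))
  cat(sprintf("  peaks: %d rows (%d blank)\n", nrow(x$peaks),
              sum(x$peaks$is_blank)))
  invisible(x)
}

#' Write a dataset's on-disk artifacts
#'
#' Writes `peaks.csv` (all methods and blanks in one peak table),
#' `library.msp` and `metadata.csv` into `dir`.
#'
#' @param dataset A `"vc_dataset"` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "vc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peak_table(dataset$peaks, file.path(dir, "peaks.csv"))
  write_msp_library(dataset$library, file.path(dir, "library.msp"))
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
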