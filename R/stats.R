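## Relative areas and the common-vs-unique abundance model
## --------------------------------------------------------
## A peak's relative area is its area divided by the "peak sum" — the sum
## of all peak areas in its chromatogram. Whether compounds shared between
## two methods are the more abundant ones is tested with a linear mixed
## model on natural-log relative areas: fixed effect = sample set
## (common / unique), uncorrelated random intercepts and set slopes for
## sample and for animal, fitted by maximum likelihood; the set effect is
## tested by a likelihood-ratio test against the null dropping the fixed
## effect (df = 1).

#' Relative peak areas of one chromatogram
#'
#' @param peaks Peak-table rows of a single chromatogram (one `sample_id`),
#'   all areas positive.
#' @return The input with a `relative_area` column; values sum to 1.
#' @export
relative_areas <- function(peaks) {
  if (nrow(peaks) == 0L) {
    stop("relative_areas: empty chromatogram", call. = FALSE)
  }
  if (length(unique(peaks$sample_id)) != 1L) {
    stop("relative_areas: peaks from more than one chromatogram",
         call. = FALSE)
  }
  stopifnot(all(peaks$area > 0))
  peaks$relative_area <- peaks$area / sum(peaks$area)
  peaks
}

#' Relative mean area per consensus compound
#'
#' Computes per-chromatogram relative areas over all animal-sample peaks of
#' the method, then averages each cluster's member-peak relative areas.
#'
#' @param profile A `"vc_profile"` or `"vc_annotated_profile"`.
#' @param peaks The method's full animal-sample peak table (the peak sum is
#'   taken over every integrated peak of each chromatogram, not only
#'   cluster members).
#' @return Numeric vector, one relative mean area per profile compound.
#' @export
cluster_relative_mean_areas <- function(profile, peaks) {
  peaks <- peaks[!peaks$is_blank, , drop = FALSE]
  peak_sum <- tapply(peaks$area, peaks$sample_id, sum)
  clusters <- get_clusters(profile)
  vapply(clusters, function(cl) {
    mp <- cl$member_peaks
    mean(mp$area / as.numeric(peak_sum[mp$sample_id]))
  }, 0)
}

#' Assemble common-vs-unique relative-area records
#'
#' Labels each compound of a profile `"common"` or `"unique"` according to
#' a cross-method match, and expands it to one record per member peak with
#' that peak's relative area in its chromatogram.
#'
#' @param profile The profile whose peaks are analysed (side A or B of the
#'   match).
#' @param match A `"vc_crossmatch"` from [match_across_methods()].
#' @param peaks The method's full animal-sample peak table.
#' @param side `"a"` or `"b"`: which side of the match `profile` is.
#' @return Data.frame: `sample_id`, `animal_id`, `cluster_index`,
#'   `relative_area`, `set_label`.
#' @export
common_unique_records <- function(profile, match, peaks, side = c("a", "b")) {
  side <- match.arg(side)
  matched <- if (side == "a") match$pairs$index_a else match$pairs$index_b
  peaks <- peaks[!peaks$is_blank, , drop = FALSE]
  peak_sum <- tapply(peaks$area, peaks$sample_id, sum)
  clusters <- get_clusters(profile)
  out <- lapply(seq_along(clusters), function(i) {
    mp <- clusters[[i]]$member_peaks
    data.frame(sample_id = mp$sample_id, animal_id = mp$animal_id,
               cluster_index = i,
               relative_area = mp$area / as.numeric(peak_sum[mp$sample_id]),
               set_label = if (i %in% matched) "common" else "unique",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mixed model for common-vs-unique compound abundance
#'
#' Fits, by maximum likelihood, `log(relative_area) ~ set_label` with
#' uncorrelated random intercepts and set-label slopes for sample and for
#' animal, and tests the fixed set-label effect with a likelihood-ratio
#' test against the null model lacking it (same random structure, df = 1).
#'
#' @param records Data.frame with columns `sample_id`, `animal_id`,
#'   `relative_area` (in (0, 1]) and `set_label`
#'   (`"common"` / `"unique"`); both labels must be present.
#' @return Object of class `"vc_lmm"`: `estimate` (log-scale common minus
#'   unique), `chi2`, `df`, `p_value`, `n_obs`, `converged`, `note`, and
#'   the two fitted `lme4` models (`full`, `null`).
#' @export
fit_common_vs_unique <- function(records) {
  needed <- c("sample_id", "animal_id", "relative_area", "set_label")
  stopifnot(all(needed %in% names(records)))
  labs <- unique(records$set_label)
  if (!all(c("common", "unique") %in% labs)) {
    stop("fit_common_vs_unique: both set labels ('common', 'unique') ",
         "must be present", call. = FALSE)
  }
  if (length(unique(records$animal_id)) < 2L ||
      length(unique(records$sample_id)) < 2L) {
    stop("fit_common_vs_unique: need >= 2 animals and >= 2 samples",
         call. = FALSE)
  }
  d <- data.frame(
    y = log(records$relative_area),
    is_common = as.numeric(records$set_label == "common"),
    sample_id = factor(records$sample_id),
    animal_id = factor(records$animal_id)
  )
  if (stats::var(d$y) == 0) {
    # constant response: null and full likelihoods coincide exactly
    return(structure(list(estimate = 0, chi2 = 0, df = 1L, p_value = 1,
                          n_obs = nrow(d), converged = TRUE,
                          note = "constant response; null = full",
                          full = NULL, null = NULL),
                     class = "vc_lmm"))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_quiet <- function(formula) {
    msgs <- character(0)
    fit <- withCallingHandlers(
      lme4::lmer(formula, data = d, REML = FALSE, control = ctrl),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, msgs = msgs)
  }
  full <- fit_quiet(
    y ~ is_common + (1 | sample_id) + (0 + is_common | sample_id) +
      (1 | animal_id) + (0 + is_common | animal_id))
  null <- fit_quiet(
    y ~ 1 + (1 | sample_id) + (0 + is_common | sample_id) +
      (1 | animal_id) + (0 + is_common | animal_id))
  ll_full <- as.numeric(stats::logLik(full$fit))
  ll_null <- as.numeric(stats::logLik(null$fit))
  chi2 <- 2 * (ll_full - ll_null)
  converged <- !length(c(full$msgs, null$msgs)) &&
    !length(full$fit@optinfo$conv$lme4$messages) &&
    !length(null$fit@optinfo$conv$lme4$messages)
  structure(list(
    estimate = unname(lme4::fixef(full$fit)["is_common"]),
    chi2 = chi2,
    df = 1L,
    p_value = stats::pchisq(max(chi2, 0), df = 1, lower.tail = FALSE),
    n_obs = nrow(d),
    converged = converged,
    note = if (converged) "" else
      paste(unique(c(full$msgs, null$msgs)), collapse = "; "),
    full = full$fit,
    null = null$fit
  ), class = "vc_lmm")
}

#' @export
print.vc_lmm <- function(x, ...) {
  cat("Common-vs-unique mixed model (ML, likelihood-ratio test)\n")
  cat(sprintf("  set effect (log scale, common - unique): %.3f\n",
              x$estimate))
  cat(sprintf("  chi2 = %.2f, df = %d, p = %.3g, n = %d\n",
              x$chi2, x$df, x$p_value, x$n_obs))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly: ",
                        x$note, "\n")
  invisible(x)
}

#' @export
summary.vc_lmm <- function(object, ...) {
  print(object)
  if (!is.null(object$full)) {
    cat("\nFull model:\n")
    print(summary(object$full), correlation = FALSE)
  }
  invisible(object)
}

#' Simulate common-vs-unique relative-area records
#'
#' Generates records under the mixed model's own data-generating process:
#' per-sample and per-animal random intercepts and set slopes, residual
#' noise, and a fixed log-scale shift of the common set. Used for
#' calibration and power checks of [fit_common_vs_unique()]. Relative areas
#' are produced by normalising exponentiated log areas within each sample,
#' so they sum to 1 per chromatogram.
#'
#' @param shift Log-scale abundance shift of the common set (0 = null).
#' @param n_animals,n_samples_per_animal Design (defaults 6 x 2).
#' @param n_common,n_unique Compounds per set (defaults 8 / 16).
#' @param sd_sample,sd_animal,sd_slope,sd_resid Variance components.
#' @param sd_compound Between-compound SD of latent log abundance
#'   (default 0: the null matches the model's own random structure, which
#'   — like the standard analysis — carries no compound-level random
#'   effect; set it positive to study the anticonservativeness that
#'   compound heterogeneity induces).
#' @param seed Optional integer seed.
#' @return Data.frame suitable for [fit_common_vs_unique()].
#' @export
simulate_area_records <- function(shift = 0, n_animals = 6,
                                  n_samples_per_animal = 2,
                                  n_common = 8, n_unique = 16,
                                  sd_sample = 0.3, sd_animal = 0.3,
                                  sd_slope = 0.05, sd_resid = 0.8,
                                  sd_compound = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  animals <- sprintf("animal_%d", seq_len(n_animals))
  b_animal <- stats::rnorm(n_animals, 0, sd_animal)
  s_animal <- stats::rnorm(n_animals, 0, sd_slope)
  base <- -6 + stats::rnorm(n_common + n_unique, 0, sd_compound)
  lab <- rep(c("common", "unique"), c(n_common, n_unique))
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (r in seq_len(n_samples_per_animal)) {
      sid <- sprintf("%s_r%d", animals[a], r)
      b_sample <- stats::rnorm(1, 0, sd_sample)
      s_sample <- stats::rnorm(1, 0, sd_slope)
      is_common <- as.numeric(lab == "common")
      log_area <- base + shift * is_common + b_animal[a] + b_sample +
        (s_animal[a] + s_sample) * is_common +
        stats::rnorm(length(base), 0, sd_resid)
      area <- exp(log_area)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, animal_id = animals[a],
        cluster_index = seq_along(base),
        relative_area = area / sum(area),
        set_label = lab, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Profile summary counts
#'
#' Table-style overview of an annotated method profile: total compounds,
#' number and percentage of volatiles, and counts per origin category.
#'
#' @param profile A `"vc_annotated_profile"`.
#' @return List of class `"vc_profile_summary"`: `method_id`, `n_total`,
#'   `n_volatile`, `pct_volatile` (`NA` for an empty profile; full
#'   precision — round for reporting), `n_by_origin` (named integer
#'   vector), `n_named`.
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "vc_annotated_profile"))
  vol <- vapply(profile$compounds, `[[`, "", "volatility")
  origin <- vapply(profile$compounds, `[[`, "", "origin_class")
  n_total <- length(profile$compounds)
  n_volatile <- sum(vol == "volatile")
  structure(list(
    method_id = profile$method_id,
    n_total = n_total,
    n_volatile = n_volatile,
    pct_volatile = if (n_total == 0L) NA_real_ else
      100 * n_volatile / n_total,
    n_by_origin = vapply(ORIGIN_LEVELS, function(l) sum(origin == l),
                         0L),
    n_named = sum(!is.na(vapply(profile$compounds, `[[`, "", "name")))
  ), class = "vc_profile_summary")
}

#' @export
print.vc_profile_summary <- function(x, ...) {
  pct <- if (is.na(x$pct_volatile)) "NA" else
    sprintf("%.0f%%", x$pct_volatile)
  cat(sprintf("Method %s: %d compounds, %d volatile (%s), %d named\n",
              x$method_id, x$n_total, x$n_volatile, pct, x$n_named))
  cat("  origin:",
      paste(sprintf("%s %d", names(x$n_by_origin), x$n_by_origin),
            collapse = ", "), "\n")
  invisible(x)
}
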