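## Annotation: library identity, volatility, origin
## ------------------------------------------------
## A consensus compound is named after a library entry only when that entry
## is the top-scoring hit, above the match-factor threshold, in a majority
## of the cluster's member samples — the per-RT-range reading of the
## majority rule. Volatility splits at a boiling point of 250 degC (strictly
## below = volatile); origin comes from a curated metadata lookup.

#' Classify compound volatility by boiling point
#'
#' @param boiling_point_c Boiling point(s), degC at 760 mmHg.
#' @param threshold_c Volatility threshold (default 250). Values strictly
#'   below are `"volatile"`; the boundary itself is `"semi_or_nonvolatile"`
#'   since volatility is defined by the strict inequality.
#' @return Character vector of labels.
#' @export
classify_volatility <- function(boiling_point_c, threshold_c = 250) {
  if (any(!is.finite(boiling_point_c))) {
    stop("classify_volatility: non-finite boiling point", call. = FALSE)
  }
  ifelse(boiling_point_c < threshold_c, "volatile", "semi_or_nonvolatile")
}

#' Classify compound origin from a metadata lookup
#'
#' @param name Compound name(s); matching is case-insensitive.
#' @param metadata_map Lookup from [read_compound_metadata()].
#' @return Origin class per name; names absent from the map are
#'   `"unclassified"`.
#' @export
classify_origin <- function(name, metadata_map) {
  vapply(tolower(trimws(name)), function(k) {
    e <- metadata_map[[k]]
    if (is.null(e)) "unclassified" else e$origin_class
  }, "", USE.NAMES = FALSE)
}

#' Annotate a consensus cluster against a spectral library
#'
#' Each member peak's spectrum is scored against every library entry with
#' [spectral_match_score()]. The cluster is named after a library entry iff
#' that entry is the top hit with score `> min_score` in more than
#' `majority_frac` of the cluster's member samples (ties on the vote count
#' broken by higher mean winning score); otherwise the compound stays
#' unknown. The reported `match_score` is the mean of the winning scores.
#' Boiling point is taken from the metadata (fallback: the library entry),
#' and volatility and origin classes are derived from it.
#'
#' @param cluster A `"vc_cluster"`.
#' @param library Spectral library, as from [read_msp_library()].
#' @param metadata_map Optional metadata lookup from
#'   [read_compound_metadata()].
#' @param min_score Match-factor threshold (default 700).
#' @param majority_frac Required fraction of member samples (default 0.5,
#'   strict majority).
#' @param mz_tol m/z tolerance for spectral matching.
#' @return An object of class `"vc_annotated"`: list with `cluster`, `name`
#'   (or `NA`), `match_score` (or `NA`), `boiling_point_c` (or `NA`),
#'   `volatility` (`volatile` / `semi_or_nonvolatile` / `unknown`) and
#'   `origin_class`.
#' @export
annotate_cluster <- function(cluster, library, metadata_map = NULL,
                             min_score = 700, majority_frac = 0.5,
                             mz_tol = 0.3) {
  stopifnot(inherits(cluster, "vc_cluster"))
  if (!length(library)) {
    stop("annotate_cluster: empty library", call. = FALSE)
  }
  peaks <- cluster$member_peaks
  votes <- character(0)
  scores <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    spec <- decode_spectrum(peaks$spectrum[i])
    if (nrow(spec) == 0L) next
    s <- vapply(library, function(e) {
      spectral_match_score(spec, e$spectrum, mz_tol = mz_tol)
    }, 0L)
    top <- which.max(s)
    if (s[top] > min_score) {
      votes <- c(votes, library[[top]]$name)
      scores <- c(scores, s[top])
    }
  }
  name <- NA_character_; match_score <- NA_real_
  if (length(votes)) {
    tab <- table(votes)
    lead <- names(tab)[tab == max(tab)]
    if (length(lead) > 1L) {  # tie on votes -> higher mean winning score
      ms <- vapply(lead, function(nm) mean(scores[votes == nm]), 0)
      lead <- lead[which.max(ms)]
    }
    if (max(tab) > majority_frac * cluster$n_samples_present) {
      name <- lead
      match_score <- round(mean(scores[votes == lead]))
    }
  }
  bp <- NA_real_
  origin <- "unclassified"
  if (!is.na(name)) {
    if (!is.null(metadata_map)) {
      e <- metadata_map[[tolower(name)]]
      if (!is.null(e)) {
        bp <- e$boiling_point_c
        origin <- e$origin_class
      }
    }
    if (is.na(bp)) {
      hit <- Find(function(e) identical(e$name, name), library)
      if (!is.null(hit) && !is.na(hit$boiling_point_c)) {
        bp <- hit$boiling_point_c
      }
    }
  }
  volatility <- if (is.na(bp)) "unknown" else classify_volatility(bp)
  structure(list(cluster = cluster, name = name, match_score = match_score,
                 boiling_point_c = bp, volatility = volatility,
                 origin_class = origin),
            class = "vc_annotated")
}

#' @export
print.vc_annotated <- function(x, ...) {
  cat(sprintf("<%s @ %.3f min: %s, bp %s degC, %s>\n",
              x$cluster$method_id, x$cluster$rt_center,
              if (is.na(x$name)) "unknown" else
                sprintf("%s (Mt %d)", x$name, x$match_score),
              if (is.na(x$boiling_point_c)) "?" else
                format(x$boiling_point_c, digits = 4),
              paste(x$volatility, x$origin_class, sep = " / ")))
  invisible(x)
}

#' Annotate every compound of a method profile
#'
#' @param profile A `"vc_profile"` from [build_method_profile()].
#' @inheritParams annotate_cluster
#' @return An object of class `"vc_annotated_profile"`: the profile with
#'   `compounds` replaced by a list of `"vc_annotated"` objects.
#' @export
annotate_profile <- function(profile, library, metadata_map = NULL,
                             min_score = 700, majority_frac = 0.5,
                             mz_tol = 0.3) {
  stopifnot(inherits(profile, "vc_profile"))
  ann <- lapply(profile$compounds, annotate_cluster, library = library,
                metadata_map = metadata_map, min_score = min_score,
                majority_frac = majority_frac, mz_tol = mz_tol)
  out <- profile
  out$compounds <- ann
  class(out) <- "vc_annotated_profile"
  out
}

#' @export
print.vc_annotated_profile <- function(x, ...) {
  named <- sum(!is.na(vapply(x$compounds, `[[`, "", "name")))
  cat(sprintf(
    "<annotated profile %s: %d compounds, %d named, %d volatile>\n",
    x$method_id, length(x$compounds), named,
    sum(vapply(x$compounds, `[[`, "", "volatility") == "volatile")))
  invisible(x)
}

#' Flatten an annotated profile to a data.frame
#'
#' @param profile A `"vc_annotated_profile"`.
#' @return One row per compound: RT center, name, match score, boiling
#'   point, volatility and origin class, mean area, occurrence.
#' @export
annotations_as_data_frame <- function(profile) {
  stopifnot(inherits(profile, "vc_annotated_profile"))
  if (!length(profile$compounds)) {
    return(data.frame(method_id = character(), rt_center = numeric(),
                      name = character(), match_score = numeric(),
                      boiling_point_c = numeric(), volatility = character(),
                      origin_class = character(), mean_area = numeric(),
                      n_samples_present = integer()))
  }
  do.call(rbind, lapply(profile$compounds, function(a) {
    data.frame(method_id = a$cluster$method_id,
               rt_center = a$cluster$rt_center,
               name = a$name, match_score = a$match_score,
               boiling_point_c = a$boiling_point_c,
               volatility = a$volatility, origin_class = a$origin_class,
               mean_area = a$cluster$mean_area,
               n_samples_present = a$cluster$n_samples_present,
               stringsAsFactors = FALSE)
  }))
}
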