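## Consensus "RT ranges"
## ---------------------
## A consensus compound of one method is the set of peaks recurring within a
## narrow retention-time span across that method's samples. "Narrow span" is
## operationalized as gap-based single linkage: sorted peaks are split
## wherever consecutive RTs differ by more than rt_tol, which is exactly the
## transitive closure of the relation |rt_i - rt_j| <= rt_tol.

new_cluster <- function(method_id, peaks, mz_tol = 0.3) {
  rt <- peaks$rt_min
  structure(list(
    method_id = method_id,
    rt_center = stats::median(rt),
    rt_lo = min(rt),
    rt_hi = max(rt),
    member_peaks = peaks,
    n_samples_present = length(unique(peaks$sample_id)),
    mean_area = mean(peaks$area),
    consensus_spectrum = consensus_spectrum(
      lapply(peaks$spectrum, decode_spectrum), mz_tol = mz_tol)
  ), class = "vc_cluster")
}

#' @export
print.vc_cluster <- function(x, ...) {
  cat(sprintf(
    "<RT range %s: center %.3f min [%.3f, %.3f], %d peaks / %d samples, mean area %.3g>\n",
    x$method_id, x$rt_center, x$rt_lo, x$rt_hi, nrow(x$member_peaks),
    x$n_samples_present, x$mean_area))
  invisible(x)
}

#' Cluster one method's peaks into consensus RT ranges
#'
#' Gap-based single-linkage clustering of retention times: after sorting,
#' a new cluster starts wherever the gap to the previous peak exceeds
#' `rt_tol`. Within a cluster at most one peak per sample is kept as a
#' member: if a sample contributes several peaks, the one nearest the
#' cluster median stays (ties toward earlier RT) and the surplus peaks are
#' reassigned to the nearest adjacent cluster.
#'
#' @param peaks Peak-table data.frame, all rows sharing one `method_id`.
#' @param rt_tol Linkage gap threshold in minutes (default 0.05).
#' @param mz_tol m/z tolerance used when forming consensus spectra.
#' @return List of `"vc_cluster"` objects sorted by `rt_center`.
#' @export
cluster_rt_ranges <- function(peaks, rt_tol = 0.05, mz_tol = 0.3) {
  stopifnot(rt_tol > 0)
  if (nrow(peaks) == 0L) return(list())
  if (length(unique(peaks$method_id)) != 1L) {
    stop("cluster_rt_ranges: peaks from more than one method", call. = FALSE)
  }
  method_id <- peaks$method_id[1L]
  o <- order(peaks$rt_min)
  peaks <- peaks[o, , drop = FALSE]
  grp <- cumsum(c(1, diff(peaks$rt_min) > rt_tol))
  assignment <- resolve_sample_duplicates(peaks, grp)
  clusters <- lapply(sort(unique(assignment)), function(g) {
    new_cluster(method_id, peaks[assignment == g, , drop = FALSE],
                mz_tol = mz_tol)
  })
  clusters[order(vapply(clusters, `[[`, 0, "rt_center"))]
}

## one compound yields one peak per chromatogram: inside each cluster keep,
## per sample, the peak nearest the cluster median (ties -> earlier RT) and
## push the rest to the nearest cluster not already holding that sample
## (falling back to a new singleton cluster). Each move strictly reduces the
## number of violations, so this terminates with at most one peak per sample
## per cluster.
resolve_sample_duplicates <- function(peaks, grp) {
  assignment <- grp
  next_id <- max(grp) + 1L
  repeat {
    centers <- vapply(split(peaks$rt_min, assignment), stats::median, 0)
    ids <- as.numeric(names(centers))
    viol <- NULL
    for (g in ids) {
      idx <- which(assignment == g)
      dup <- peaks$sample_id[idx][duplicated(peaks$sample_id[idx])]
      if (length(dup)) {
        viol <- list(g = g, idx = idx, s = dup[1L])
        break
      }
    }
    if (is.null(viol)) break
    cand <- viol$idx[peaks$sample_id[viol$idx] == viol$s]
    d <- abs(peaks$rt_min[cand] - centers[as.character(viol$g)])
    keep <- cand[order(d, peaks$rt_min[cand])][1L]
    move <- setdiff(cand, keep)[1L]
    elig <- ids[vapply(ids, function(h) {
      h != viol$g &&
        !(viol$s %in% peaks$sample_id[assignment == h])
    }, TRUE)]
    if (length(elig)) {
      ec <- centers[as.character(elig)]
      dist <- abs(ec - peaks$rt_min[move])
      assignment[move] <- elig[order(dist, ec)][1L]
    } else {
      assignment[move] <- next_id
      next_id <- next_id + 1L
    }
  }
  assignment
}

#' Occurrence filter
#'
#' Retains clusters present in at least `min_frac` of the method's samples
#' (default: at least half), i.e. `n_samples_present >=
#' ceiling(min_frac * n_samples_total)`.
#'
#' @param clusters List of `"vc_cluster"`s.
#' @param n_samples_total Number of animal samples analysed for the method.
#' @param min_frac Minimum occurrence fraction in (0, 1].
#' @return The retained clusters, order preserved.
#' @export
occurrence_filter <- function(clusters, n_samples_total, min_frac = 0.5) {
  stopifnot(min_frac > 0, min_frac <= 1)
  if (n_samples_total < 1) {
    stop("occurrence_filter: n_samples_total must be >= 1", call. = FALSE)
  }
  need <- ceiling(min_frac * n_samples_total)
  Filter(function(cl) cl$n_samples_present >= need, clusters)
}

#' Blank correction
#'
#' Compares each animal-sample cluster against blank-sample clusters of the
#' same method: a cluster is kept if no blank cluster lies within `rt_tol`
#' of its center, or if its mean area exceeds that of the nearest matched
#' blank cluster. Removed clusters are reported together with the blocking
#' blank cluster.
#'
#' @param animal_clusters,blank_clusters Cluster lists from the same method
#'   (animal samples and blanks clustered separately).
#' @param rt_tol RT matching tolerance in minutes.
#' @return List with `kept` (cluster list) and `removed` (data.frame:
#'   `rt_center`, `mean_area`, `blank_rt_center`, `blank_mean_area`).
#' @export
blank_filter <- function(animal_clusters, blank_clusters, rt_tol = 0.05) {
  if (!length(animal_clusters)) {
    return(list(kept = list(),
                removed = data.frame(rt_center = numeric(),
                                     mean_area = numeric(),
                                     blank_rt_center = numeric(),
                                     blank_mean_area = numeric())))
  }
  blank_centers <- vapply(blank_clusters, `[[`, 0, "rt_center")
  keep <- logical(length(animal_clusters))
  removed <- list()
  for (i in seq_along(animal_clusters)) {
    cl <- animal_clusters[[i]]
    if (length(blank_centers)) {
      d <- abs(blank_centers - cl$rt_center)
      j <- which.min(d)
    }
    if (!length(blank_centers) || d[j] > rt_tol) {
      keep[i] <- TRUE
    } else if (cl$mean_area > blank_clusters[[j]]$mean_area) {
      keep[i] <- TRUE
    } else {
      removed[[length(removed) + 1L]] <- data.frame(
        rt_center = cl$rt_center, mean_area = cl$mean_area,
        blank_rt_center = blank_clusters[[j]]$rt_center,
        blank_mean_area = blank_clusters[[j]]$mean_area)
    }
  }
  list(kept = animal_clusters[keep],
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(rt_center = numeric(), mean_area = numeric(),
                    blank_rt_center = numeric(),
                    blank_mean_area = numeric()))
}

#' Build the consensus compound profile of one method
#'
#' Runs the full per-method consensus stage: clusters the animal-sample
#' peaks and the blank peaks separately into RT ranges, applies the
#' occurrence filter to the animal clusters and then the blank correction.
#'
#' @param peaks Peak-table data.frame for one method, animal samples and
#'   blanks together.
#' @param rt_tol,min_frac,mz_tol See [cluster_rt_ranges()],
#'   [occurrence_filter()], [blank_filter()].
#' @return An object of class `"vc_profile"`: list with `method_id`,
#'   `compounds` (kept clusters, sorted by `rt_center`), `n_samples_total`,
#'   `removed_blank` (blank-correction report) and stage counts
#'   (`n_clustered`, `n_after_occurrence`).
#' @export
build_method_profile <- function(peaks, rt_tol = 0.05, min_frac = 0.5,
                                 mz_tol = 0.3) {
  stopifnot(nrow(peaks) > 0L)
  if (length(unique(peaks$method_id)) != 1L) {
    stop("build_method_profile: peaks from more than one method",
         call. = FALSE)
  }
  animal <- peaks[!peaks$is_blank, , drop = FALSE]
  blank <- peaks[peaks$is_blank, , drop = FALSE]
  n_samples_total <- length(unique(animal$sample_id))
  clusters <- cluster_rt_ranges(animal, rt_tol = rt_tol, mz_tol = mz_tol)
  occ <- occurrence_filter(clusters, n_samples_total, min_frac = min_frac)
  blank_clusters <- if (nrow(blank)) {
    cluster_rt_ranges(blank, rt_tol = rt_tol, mz_tol = mz_tol)
  } else list()
  bf <- blank_filter(occ, blank_clusters, rt_tol = rt_tol)
  kept <- bf$kept[order(vapply(bf$kept, `[[`, 0, "rt_center"))]
  structure(list(method_id = peaks$method_id[1L],
                 compounds = kept,
                 n_samples_total = n_samples_total,
                 removed_blank = bf$removed,
                 n_clustered = length(clusters),
                 n_after_occurrence = length(occ)),
            class = "vc_profile")
}

#' @export
print.vc_profile <- function(x, ...) {
  cat(sprintf(
    "<method profile %s: %d consensus compounds (%d clustered, %d after occurrence filter, %d removed by blank correction), %d samples>\n",
    x$method_id, length(x$compounds), x$n_clustered, x$n_after_occurrence,
    nrow(x$removed_blank), x$n_samples_total))
  invisible(x)
}

#' Summarise a cluster list as a data.frame
#'
#' @param clusters List of `"vc_cluster"`s (or a `"vc_profile"`).
#' @return Data.frame with one row per cluster: `method_id`, `rt_center`,
#'   `rt_lo`, `rt_hi`, `n_peaks`, `n_samples_present`, `mean_area`.
#' @export
clusters_as_data_frame <- function(clusters) {
  if (inherits(clusters, "vc_profile")) clusters <- clusters$compounds
  if (!length(clusters)) {
    return(data.frame(method_id = character(), rt_center = numeric(),
                      rt_lo = numeric(), rt_hi = numeric(),
                      n_peaks = integer(), n_samples_present = integer(),
                      mean_area = numeric()))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(method_id = cl$method_id, rt_center = cl$rt_center,
               rt_lo = cl$rt_lo, rt_hi = cl$rt_hi,
               n_peaks = nrow(cl$member_peaks),
               n_samples_present = cl$n_samples_present,
               mean_area = cl$mean_area)
  }))
}
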