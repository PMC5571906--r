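## Cross-method compound alignment
## -------------------------------
## Compounds are paired across two instruments by (a) sharing diagnostic
## fragment ions and (b) preserving elution order: among ion-sharing
## candidate pairs, the final matching is the maximum-cardinality chain that
## is strictly increasing in both retention-time sequences, found by
## longest-increasing-chain dynamic programming. Matches are validated by
## Spearman rank correlations of RTs and of relative mean areas.

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho uses average ranks for ties. For `n <= 9` the two-sided p-value is
#' computed from the exact permutation distribution of rho (all `n!`
#' pairings); for larger n the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df is used, with
#' `|rho| = 1` mapping to p = 0.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List of class `"vc_rankcor"`: `rho`, `p_value`, `n`, `method`
#'   (`"exact"` or `"t-approximation"`) and `status` (`"ok"` or
#'   `"degenerate"` when either side has zero rank variance, in which case
#'   `rho` and `p_value` are `NA`).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) {
    stop("spearman_correlation: need at least 3 pairs", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "none", status = "degenerate"),
                     class = "vc_rankcor"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    s <- as.numeric(ry_perm %*% rx)
    rho_perm <- (s / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1 - 1e-12) {
      p <- 0
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    }
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method,
                 status = "ok"),
            class = "vc_rankcor")
}

#' @export
print.vc_rankcor <- function(x, ...) {
  if (identical(x$status, "degenerate")) {
    cat(sprintf("Spearman rank correlation: N = %d, degenerate (zero rank variance)\n",
                x$n))
  } else {
    cat(sprintf("Spearman rank correlation: N = %d, rho = %.3g, p = %.3g (%s)\n",
                x$n, x$rho, x$p_value, x$method))
  }
  invisible(x)
}

## all n! permutations of 1..n, rows in a deterministic order; n <= 9 keeps
## this under ~13 MB
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  r <- nrow(sub)
  out <- matrix(0L, n * r, n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * r + 1L):(k * r)
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], r)
  }
  out
}

#' Longest elution-order-concordant subset
#'
#' Given paired retention times on two instruments, finds a maximum-size
#' subset of pairs whose elution order agrees on both sides (a longest
#' chain strictly increasing in both RT sequences). Ties between equally
#' long chains are broken deterministically toward earlier method-A
#' predecessors.
#'
#' @param rt_a,rt_b Paired retention times.
#' @return Logical vector: `TRUE` for pairs on the concordant chain.
#' @export
concordant_chain <- function(rt_a, rt_b) {
  stopifnot(length(rt_a) == length(rt_b))
  n <- length(rt_a)
  if (n == 0L) return(logical(0))
  o <- order(rt_a, rt_b)
  a <- rt_a[o]; b <- rt_b[o]
  len <- rep(1L, n); pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- a[j] < a[i] && b[j] < b[i]
      if (ok && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        pred[i] <- j
      }
    }
  }
  end <- which.max(len)
  keep_sorted <- logical(n)
  while (!is.na(end)) {
    keep_sorted[end] <- TRUE
    end <- pred[end]
  }
  keep <- logical(n)
  keep[o] <- keep_sorted
  keep
}

top_ions <- function(cluster, k) {
  spec <- cluster$consensus_spectrum
  if (nrow(spec) == 0L) return(spec)
  spec[order(-spec[, "intensity"]), , drop = FALSE][
    seq_len(min(k, nrow(spec))), , drop = FALSE]
}

get_clusters <- function(profile) {
  if (inherits(profile, "vc_annotated_profile")) {
    lapply(profile$compounds, `[[`, "cluster")
  } else if (inherits(profile, "vc_profile")) {
    profile$compounds
  } else if (is.list(profile)) {
    profile
  } else {
    stop("cannot extract clusters from object of class ",
         class(profile)[1L], call. = FALSE)
  }
}

#' Match compounds across two methods
#'
#' Candidate pairs are clusters sharing at least `n_diagnostic` of their
#' `k` most intense consensus-spectrum m/z values (within `mz_tol`). Among
#' candidates, the final pairing is the maximum-cardinality matching whose
#' pairs, sorted by retention time in method A, are also strictly
#' increasing in method B — computed by longest-increasing-chain dynamic
#' programming, ties broken toward higher summed shared-ion intensity
#' agreement. Each cluster joins at most one pair; the rest go to the
#' per-method unique sets.
#'
#' @param profile_a,profile_b `"vc_profile"` / `"vc_annotated_profile"`
#'   objects (or bare cluster lists).
#' @param mz_tol Ion-matching tolerance in u (default 0.3).
#' @param n_diagnostic Shared ions required to make a candidate pair
#'   (default 2).
#' @param k Number of most-intense ions considered per cluster (default 8).
#' @return Object of class `"vc_crossmatch"`: `pairs` (data.frame with
#'   `index_a`, `index_b`, `rt_a`, `rt_b`, `ion_1`, `ion_2`), `unique_a`,
#'   `unique_b` (integer cluster indices), `n_a`, `n_b`.
#' @export
match_across_methods <- function(profile_a, profile_b, mz_tol = 0.3,
                                 n_diagnostic = 2L, k = 8L) {
  if (n_diagnostic < 1L) stop("n_diagnostic must be >= 1", call. = FALSE)
  if (n_diagnostic > k) {
    stop("n_diagnostic (", n_diagnostic, ") exceeds the ion shortlist k (",
         k, ")", call. = FALSE)
  }
  ca <- get_clusters(profile_a)
  cb <- get_clusters(profile_b)
  if (!length(ca) || !length(cb)) {
    stop("match_across_methods: empty profile", call. = FALSE)
  }
  ions_a <- lapply(ca, top_ions, k = k)
  ions_b <- lapply(cb, top_ions, k = k)
  rt_a <- vapply(ca, `[[`, 0, "rt_center")
  rt_b <- vapply(cb, `[[`, 0, "rt_center")

  cand <- list()
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      idx <- pair_sticks(ions_a[[i]], ions_b[[j]], mz_tol)
      shared <- which(!is.na(idx))
      if (length(shared) >= n_diagnostic) {
        ia <- ions_a[[i]][shared, , drop = FALSE]
        ib <- ions_b[[j]][idx[shared], , drop = FALSE]
        agree <- sum(pmin(ia[, "intensity"] / max(ia[, "intensity"]),
                          ib[, "intensity"] / max(ib[, "intensity"])))
        ord <- order(-pmin(ia[, "intensity"], ib[, "intensity"]))
        diag_mz <- ia[ord, "mz"][seq_len(min(2L, length(ord)))]
        cand[[length(cand) + 1L]] <- list(
          i = i, j = j, agree = agree,
          ion_1 = diag_mz[1L],
          ion_2 = if (length(diag_mz) > 1L) diag_mz[2L] else NA_real_)
      }
    }
  }

  pairs <- data.frame(index_a = integer(), index_b = integer(),
                      rt_a = numeric(), rt_b = numeric(),
                      ion_1 = numeric(), ion_2 = numeric())
  if (length(cand)) {
    sel <- chain_matching(
      rt_a[vapply(cand, `[[`, 0L, "i")],
      rt_b[vapply(cand, `[[`, 0L, "j")],
      vapply(cand, `[[`, 0, "agree"))
    chosen <- cand[sel]
    if (length(chosen)) {
      pairs <- do.call(rbind, lapply(chosen, function(p) {
        data.frame(index_a = p$i, index_b = p$j,
                   rt_a = rt_a[p$i], rt_b = rt_b[p$j],
                   ion_1 = p$ion_1, ion_2 = p$ion_2)
      }))
      pairs <- pairs[order(pairs$rt_a), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  structure(list(pairs = pairs,
                 unique_a = setdiff(seq_along(ca), pairs$index_a),
                 unique_b = setdiff(seq_along(cb), pairs$index_b),
                 n_a = length(ca), n_b = length(cb)),
            class = "vc_crossmatch")
}

## maximum chain of candidate pairs strictly increasing in both RT
## coordinates; primary criterion chain length, secondary the summed
## ion-agreement score; O(m^2) DP over candidates
chain_matching <- function(rt_a, rt_b, score) {
  m <- length(rt_a)
  if (m == 0L) return(integer(0))
  o <- order(rt_a, rt_b)
  a <- rt_a[o]; b <- rt_b[o]; s <- score[o]
  len <- rep(1L, m); tot <- s; pred <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      if (a[j] < a[i] && b[j] < b[i]) {
        better <- (len[j] + 1L > len[i]) ||
          (len[j] + 1L == len[i] && tot[j] + s[i] > tot[i])
        if (better) {
          len[i] <- len[j] + 1L
          tot[i] <- tot[j] + s[i]
          pred[i] <- j
        }
      }
    }
  }
  best <- which(len == max(len))
  end <- best[which.max(tot[best])]
  sel <- integer(0)
  while (!is.na(end)) {
    sel <- c(end, sel)
    end <- pred[end]
  }
  sort(o[sel])
}

#' @export
print.vc_crossmatch <- function(x, ...) {
  cat(sprintf("<cross-method match: %d pairs, %d unique to A (of %d), %d unique to B (of %d)>\n",
              nrow(x$pairs), length(x$unique_a), x$n_a,
              length(x$unique_b), x$n_b))
  invisible(x)
}

#' Retention-time rank correlation of matched compounds
#'
#' @param match A `"vc_crossmatch"`, or a data.frame with columns `rt_a`
#'   and `rt_b`.
#' @return A `"vc_rankcor"` (see [spearman_correlation()]).
#' @export
rt_rank_correlation <- function(match) {
  pairs <- if (inherits(match, "vc_crossmatch")) match$pairs else match
  if (nrow(pairs) < 3L) {
    stop("rt_rank_correlation: fewer than 3 matched pairs", call. = FALSE)
  }
  spearman_correlation(pairs$rt_a, pairs$rt_b)
}

#' Relative-mean-area rank correlation of matched compounds
#'
#' @param match A `"vc_crossmatch"`.
#' @param rel_area_a,rel_area_b Relative mean area per cluster of profile A
#'   / B (as from [cluster_relative_mean_areas()]), indexed like the
#'   profiles given to [match_across_methods()].
#' @return A `"vc_rankcor"`; degenerate (rho `NA`) when either side has
#'   zero rank variance.
#' @export
area_rank_correlation <- function(match, rel_area_a, rel_area_b) {
  stopifnot(inherits(match, "vc_crossmatch"))
  if (nrow(match$pairs) < 3L) {
    stop("area_rank_correlation: fewer than 3 matched pairs", call. = FALSE)
  }
  spearman_correlation(rel_area_a[match$pairs$index_a],
                       rel_area_b[match$pairs$index_b])
}

#' Retrieval of confirmed compounds in another method's profile
#'
#' How many of a set of identity-confirmed compounds (e.g. confirmed by
#' running authentic standards on one adsorbent) reappear among the
#' annotations of another method's profile. Name matching is
#' case-insensitive.
#'
#' @param confirmed_names Character vector of confirmed compound names.
#' @param target_profile A `"vc_annotated_profile"` (or character vector of
#'   annotated names).
#' @return List: `n_searched`, `n_retrieved`, `fraction`, `retrieved`
#'   (logical per name).
#' @export
adsorbent_retrieval <- function(confirmed_names, target_profile) {
  if (!length(confirmed_names)) {
    stop("adsorbent_retrieval: empty confirmed set", call. = FALSE)
  }
  target_names <- if (is.character(target_profile)) {
    target_profile
  } else {
    vapply(target_profile$compounds, `[[`, "", "name")
  }
  target_names <- tolower(target_names[!is.na(target_names)])
  hit <- tolower(trimws(confirmed_names)) %in% target_names
  list(n_searched = length(confirmed_names),
       n_retrieved = sum(hit),
       fraction = sum(hit) / length(confirmed_names),
       retrieved = stats::setNames(hit, confirmed_names))
}
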