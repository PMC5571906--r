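#' Encode a stick spectrum as a compact string
#'
#' Spectra travel inside peak-table CSVs as space-separated `mz:intensity`
#' pairs (e.g. `"43:999 57:420"`). Encoding uses [format()] with 15
#' significant digits so finite decimal inputs round-trip exactly.
#'
#' @param spectrum Two-column numeric matrix with columns `mz` and
#'   `intensity`.
#' @return A single character string; `""` for a zero-row spectrum.
#' @seealso [decode_spectrum()]
#' @export
encode_spectrum <- function(spectrum) {
  spectrum <- as_spectrum(spectrum)
  if (nrow(spectrum) == 0L) return("")
  paste(
    paste0(
      format(spectrum[, "mz"], trim = TRUE, digits = 15, scientific = FALSE),
      ":",
      format(spectrum[, "intensity"], trim = TRUE, digits = 15,
             scientific = FALSE)
    ),
    collapse = " "
  )
}

#' Decode a stick-spectrum string
#'
#' @param x Character string of space-separated `mz:intensity` pairs.
#' @return Two-column numeric matrix (`mz`, `intensity`), rows in input
#'   order.
#' @export
decode_spectrum <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (is.na(x) || !nzchar(x)) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("mz", "intensity"))))
  }
  parts <- strsplit(strsplit(x, "[[:space:]]+")[[1L]], ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed spectrum token(s): ",
         paste(vapply(parts[bad], paste, "", collapse = ":"), collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("mz", "intensity")))
  if (anyNA(m)) stop("non-numeric value in spectrum string", call. = FALSE)
  m
}

## Coerce list(c(mz, intensity), ...) / data.frame / matrix to the canonical
## two-column matrix form used internally.
as_spectrum <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    m <- as.matrix(x[, c("mz", "intensity")])
  } else if (is.list(x)) {
    m <- do.call(rbind, x)
  } else {
    stop("cannot interpret object of class '", class(x)[1L],
         "' as a spectrum", call. = FALSE)
  }
  if (length(m) == 0L) {
    m <- matrix(numeric(0), ncol = 2L)
  }
  if (ncol(m) != 2L) stop("a spectrum needs exactly 2 columns", call. = FALSE)
  colnames(m) <- c("mz", "intensity")
  storage.mode(m) <- "double"
  m
}

## Greedy nearest-m/z pairing between two spectra within mz_tol.
## Returns an integer vector idx of length nrow(a): idx[i] = matching row of
## b or NA. Pairs are formed best-first (smallest |delta mz|), each stick
## used at most once.
pair_sticks <- function(a, b, mz_tol) {
  na <- nrow(a); nb <- nrow(b)
  idx <- rep(NA_integer_, na)
  if (na == 0L || nb == 0L) return(idx)
  d <- abs(outer(a[, "mz"], b[, "mz"], "-"))
  d[d > mz_tol] <- NA
  while (any(!is.na(d))) {
    k <- arrayInd(which.min(d), dim(d))
    idx[k[1L]] <- k[2L]
    d[k[1L], ] <- NA
    d[, k[2L]] <- NA
  }
  idx
}

#' NIST-style spectral match factor
#'
#' Similarity between two stick spectra on the familiar 0--999 library-search
#' scale. Each stick is weighted as `intensity^int_power * mz^mz_power`
#' (defaults 0.5 and 1, the classic dot-product weighting for electron-impact
#' spectra, which up-weights the more diagnostic high-m/z fragments). Sticks
#' are paired greedily by nearest m/z within `mz_tol`; unpaired sticks
#' contribute nothing to the overlap but still count in the norms, so
#' `score(x, x) == 999` and disjoint spectra score 0.
#'
#' @param query,reference Stick spectra (two-column `mz`/`intensity`
#'   matrices, or anything [as_spectrum()] understands). Both must be
#'   non-empty.
#' @param mz_tol m/z pairing tolerance in u (default 0.3, suited to
#'   unit-resolution quadrupole data).
#' @param int_power,mz_power Weighting exponents.
#' @return Integer score in `[0, 999]` (round of 999 x weighted cosine).
#' @examples
#' s <- cbind(mz = c(91, 92), intensity = c(999, 600))
#' spectral_match_score(s, s)  # 999
#' @export
spectral_match_score <- function(query, reference, mz_tol = 0.3,
                                 int_power = 0.5, mz_power = 1) {
  query <- as_spectrum(query)
  reference <- as_spectrum(reference)
  if (nrow(query) == 0L || nrow(reference) == 0L) {
    stop("spectral_match_score: empty spectrum", call. = FALSE)
  }
  stopifnot(mz_tol > 0)
  wq <- query[, "intensity"]^int_power * query[, "mz"]^mz_power
  wr <- reference[, "intensity"]^int_power * reference[, "mz"]^mz_power
  idx <- pair_sticks(query, reference, mz_tol)
  paired <- !is.na(idx)
  dot <- sum(wq[paired] * wr[idx[paired]])
  denom <- sqrt(sum(wq^2) * sum(wr^2))
  as.integer(round(999 * dot / denom))
}

#' Consensus spectrum of a set of member spectra
#'
#' Merges the stick spectra of a cluster's member peaks: m/z values are
#' grouped by single-linkage within `mz_tol` and each group is summarised by
#' its mean m/z and mean intensity (absent sticks count as 0, so intensities
#' reflect prevalence as well as height). Output sorted by m/z.
#'
#' @param spectra List of stick spectra.
#' @param mz_tol Grouping tolerance in u.
#' @return A stick-spectrum matrix.
#' @export
consensus_spectrum <- function(spectra, mz_tol = 0.3) {
  spectra <- lapply(spectra, as_spectrum)
  all <- do.call(rbind, spectra)
  if (is.null(all) || nrow(all) == 0L) {
    return(as_spectrum(matrix(numeric(0), ncol = 2L)))
  }
  o <- order(all[, "mz"])
  all <- all[o, , drop = FALSE]
  grp <- cumsum(c(1, diff(all[, "mz"]) > mz_tol))
  mz <- tapply(all[, "mz"], grp, mean)
  total <- tapply(all[, "intensity"], grp, sum)
  out <- cbind(mz = as.numeric(mz),
               intensity = as.numeric(total) / length(spectra))
  out[order(out[, "mz"]), , drop = FALSE]
}
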