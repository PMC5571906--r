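## On-disk dialects
## ----------------
## Peak table: UTF-8 CSV, header required, columns
##   sample_id,animal_id,method_id,is_blank,rt_min,area,spectrum
## with the spectrum encoded as space-separated mz:intensity pairs.
## MSP: NIST text dialect -- records separated by blank lines, each with
##   Name: / optional CAS: / optional BP: / Num Peaks: then "mz intensity"
##   stick pairs, several per line allowed, separated by ";".
## Metadata: CSV with columns compound_id,name,cas,boiling_point_c,origin_class.

PEAK_COLUMNS <- c("sample_id", "animal_id", "method_id", "is_blank",
                  "rt_min", "area", "spectrum")

#' Read a peak table
#'
#' @param path Path to a peak-table CSV (see package README for the dialect).
#' @return A data.frame with columns `sample_id`, `animal_id`, `method_id`
#'   (character), `is_blank` (logical), `rt_min`, `area` (numeric) and
#'   `spectrum` (encoded string, see [decode_spectrum()]). Blank samples have
#'   `animal_id == ""`.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(PEAK_COLUMNS, names(df))
  if (length(missing)) {
    stop("peak table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, PEAK_COLUMNS]
  df$is_blank <- df$is_blank %in% c("true", "TRUE", "True", "1")
  df$rt_min <- as.numeric(df$rt_min)
  df$area <- as.numeric(df$area)
  validate_peaks(df, path)
  df
}

validate_peaks <- function(df, label = "peak table") {
  bad <- which(!is.finite(df$rt_min) | df$rt_min <= 0 |
                 !is.finite(df$area) | df$area <= 0)
  if (length(bad)) {
    stop(label, ": non-positive or non-numeric rt_min/area at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad_blank <- which(df$is_blank & nzchar(df$animal_id))
  if (length(bad_blank)) {
    stop(label, ": blank rows must have empty animal_id (row(s) ",
         paste(utils::head(bad_blank, 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(df)
}

#' Write a peak table
#'
#' @param peaks Data.frame as returned by [read_peak_table()].
#' @param path Output CSV path.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(all(PEAK_COLUMNS %in% names(peaks)))
  out <- peaks[, PEAK_COLUMNS]
  out$is_blank <- ifelse(out$is_blank, "true", "false")
  out$rt_min <- format(out$rt_min, trim = TRUE, digits = 15,
                       scientific = FALSE)
  out$area <- format(out$area, trim = TRUE, digits = 15, scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MSP spectral library
#'
#' Parses the NIST text dialect: blank-line-separated records with `Name:`,
#' optional `CAS:` and `BP:` fields, a `Num Peaks:` count and stick lines of
#' whitespace-separated `mz intensity` pairs (multiple pairs per line may be
#' separated by `;`).
#'
#' @param path Path to the `.msp` file.
#' @return A list of library entries, each a list with `name`, `cas` (or
#'   `NA`), `boiling_point_c` (or `NA`) and `spectrum` (matrix).
#' @export
read_msp_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  blocks <- split(lines, cumsum(!nzchar(lines)))
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- Filter(length, blocks)
  lapply(blocks, parse_msp_record)
}

parse_msp_record <- function(block) {
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), block, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^[^:]+:", "", hit[1L]))
  }
  name <- field("Name")
  if (is.na(name)) stop("MSP record without a Name: field", call. = FALSE)
  n_declared <- field("Num Peaks")
  if (is.na(n_declared)) {
    stop("MSP record '", name, "' has no Num Peaks: field", call. = FALSE)
  }
  n_declared <- as.integer(n_declared)
  stick_lines <- block[!grepl("^[A-Za-z][A-Za-z0-9 #_]*:", block)]
  tokens <- unlist(strsplit(stick_lines, ";", fixed = TRUE))
  tokens <- tokens[nzchar(trimws(tokens))]
  vals <- as.numeric(unlist(strsplit(trimws(tokens), "[[:space:]]+")))
  if (length(vals) %% 2L != 0L || anyNA(vals)) {
    stop("MSP record '", name, "': malformed stick lines", call. = FALSE)
  }
  spec <- matrix(vals, ncol = 2L, byrow = TRUE,
                 dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(spec) != n_declared) {
    stop("MSP record '", name, "': Num Peaks is ", n_declared,
         " but ", nrow(spec), " sticks were found", call. = FALSE)
  }
  bp <- field("BP")
  list(name = name,
       cas = field("CAS"),
       boiling_point_c = if (is.na(bp)) NA_real_ else as.numeric(bp),
       spectrum = spec)
}

#' Write an MSP spectral library
#'
#' @param library List of entries as returned by [read_msp_library()].
#' @param path Output path.
#' @export
write_msp_library <- function(library, path) {
  fmt <- function(x) format(x, trim = TRUE, digits = 15, scientific = FALSE)
  txt <- vapply(library, function(e) {
    hdr <- paste0("Name: ", e$name)
    if (!is.null(e$cas) && !is.na(e$cas)) {
      hdr <- c(hdr, paste0("CAS: ", e$cas))
    }
    if (!is.null(e$boiling_point_c) && !is.na(e$boiling_point_c)) {
      hdr <- c(hdr, paste0("BP: ", fmt(e$boiling_point_c)))
    }
    spec <- as_spectrum(e$spectrum)
    sticks <- paste(fmt(spec[, "mz"]), fmt(spec[, "intensity"]))
    paste(c(hdr, paste0("Num Peaks: ", nrow(spec)), sticks, ""),
          collapse = "\n")
  }, "")
  writeLines(txt, path)
  invisible(path)
}

## origin-class alias normalization; anything unrecognized is unclassified
ORIGIN_LEVELS <- c("exogenous", "potentially_endogenous",
                   "potentially_metabolized", "unclassified")

#' Normalize origin-class labels
#'
#' Maps the abbreviations used in compound tables (`exo`, `pot endo`,
#' `pot metab`, `pot met`, ...) onto the four canonical origin categories;
#' unrecognized strings become `"unclassified"`.
#'
#' @param x Character vector of origin labels.
#' @return Character vector over
#'   `c("exogenous", "potentially_endogenous", "potentially_metabolized",
#'   "unclassified")`.
#' @export
normalize_origin <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(x)))
  out <- rep("unclassified", length(x))
  out[key %in% c("exo", "exogenous")] <- "exogenous"
  out[key %in% c("pot_endo", "potentially_endogenous", "endo",
                 "endogenous")] <- "potentially_endogenous"
  out[key %in% c("pot_metab", "pot_met", "potentially_metabolized",
                 "metabolized")] <- "potentially_metabolized"
  out
}

## "95±3" / "175±20" -> 95 / 175: classification uses the central value
parse_boiling_point <- function(x) {
  as.numeric(sub("±.*$", "", trimws(as.character(x))))
}

#' Read a compound-metadata table
#'
#' @param path CSV with columns `name`, `boiling_point_c`, `origin_class`
#'   (a `compound_id` / `cas` column may be present and is carried along).
#'   Boiling points may carry a `±` uncertainty; only the central value is
#'   kept. Lookup is case-insensitive on the compound name.
#' @return A named list keyed by lowercased name; each element is
#'   `list(boiling_point_c =, origin_class =)`.
#' @export
read_compound_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("name", "boiling_point_c", "origin_class"), names(df))
  if (length(missing)) {
    stop("metadata ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bp <- parse_boiling_point(df$boiling_point_c)
  origin <- normalize_origin(df$origin_class)
  key <- tolower(trimws(df$name))
  out <- list()
  for (i in seq_along(key)) {
    entry <- list(boiling_point_c = bp[i], origin_class = origin[i])
    if (!is.null(out[[key[i]]])) {
      if (!identical(out[[key[i]]], entry)) {
        stop("metadata ", path, ": duplicate name '", df$name[i],
             "' with conflicting values", call. = FALSE)
      }
    } else {
      out[[key[i]]] <- entry
    }
  }
  out
}

#' Compounds detected in common by the mobile GC-MS and TD tube Mix methods
#'
#' The 18 tentatively library-identified volatiles found by both the mobile
#' GC-MS and the thermal-desorption (Tenax TA + XAD-2 mix) method in a
#' marmoset body-odor method-comparison study, with the printed boiling
#' points (central values, degC at 760 mmHg), per-method retention times
#' (min) and mean peak areas, mean library match factor, and origin
#' category. Ships with the package as a worked example for the
#' rank-correlation and classification steps.
#'
#' @return A data.frame with one row per compound and columns `name`,
#'   `boiling_point_c`, `rt_mobile_min`, `area_mobile`, `match_factor`,
#'   `rt_td_min`, `area_td`, `origin_class`.
#' @export
common_volatiles <- function() {
  path <- system.file("extdata", "common_volatiles.csv",
                      package = "vocompare", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  df$origin_class <- normalize_origin(df$origin_class)
  df
}
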