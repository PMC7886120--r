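#' Read longitudinal claims records from delimited text
#'
#' Reads a long-format claims file (one diagnosis event per row) into a
#' claims table. The delimiter is chosen from the file extension
#' (`.tsv`/`.txt` are tab-separated, anything else comma-separated) and the
#' column names holding the patient identifier, diagnosis code and service
#' date are configurable, so files exported from different claims systems
#' can be read without reshaping.
#'
#' Codes are whitespace-trimmed and upper-cased on ingestion; dates must be
#' ISO-8601 (`YYYY-MM-DD`). Duplicate (patient, code, date) rows are kept:
#' repeat claims are legitimate and collapse later under set semantics.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param patient_col,code_col,date_col Names of the columns holding the
#'   patient identifier, ICD-10 code and service date. Defaults
#'   `"patient_id"`, `"code"`, `"date"`.
#' @return A tibble with columns `patient_id` (character), `code`
#'   (character, trimmed and upper-cased) and `date` (`Date`), one row per
#'   claims record.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,code,date", "p1,F320,2012-03-01",
#'              "p1,g47,2011-06-15"), f)
#' read_claims(f)
#' @export
read_claims <- function(path, patient_col = "patient_id", code_col = "code",
                        date_col = "date") {
  if (!file.exists(path)) {
    stop("claims file not found: ", path, call. = FALSE)
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  for (col in c(patient_col, code_col, date_col)) {
    if (!col %in% names(raw)) {
      stop("claims file ", path, " has no column '", col,
           "'; available: ", paste(names(raw), collapse = ", "), call. = FALSE)
    }
  }
  dates <- as.Date(raw[[date_col]], format = "%Y-%m-%d")
  bad <- which(is.na(dates) | is.na(raw[[date_col]]))
  if (length(bad) > 0) {
    stop("unparseable date '", raw[[date_col]][bad[1]], "' at data row ",
         bad[1], " (line ", bad[1] + 1L, ") of ", path, call. = FALSE)
  }
  codes <- toupper(trimws(raw[[code_col]]))
  if (any(!nzchar(codes))) {
    stop("empty diagnosis code at data row ", which(!nzchar(codes))[1],
         " of ", path, call. = FALSE)
  }
  tibble::tibble(
    patient_id = as.character(raw[[patient_col]]),
    code = codes,
    date = dates
  )
}

#' Truncate an ICD-10 code to its 3-character category
#'
#' All analyses aggregate diagnoses to the 3-character ICD-10 category
#' (e.g. `"F320"` and `"F32.9"` both map to `"F32"`), the granularity at
#' which category-level disease names are defined. Codes shorter than three
#' characters are returned unchanged (upper-cased) with a one-time warning.
#'
#' @param code Character vector of ICD-10 codes (category or full).
#' @return Character vector of 3-character categories.
#' @examples
#' truncate_code(c("F320", "f32", "K29.1"))
#' @export
truncate_code <- function(code) {
  if (any(!nzchar(code))) stop("empty diagnosis code", call. = FALSE)
  code <- toupper(trimws(code))
  short <- nchar(code) < 3L
  if (any(short)) {
    warning("code(s) shorter than 3 characters returned unchanged: ",
            paste(unique(code[short]), collapse = ", "), call. = FALSE)
  }
  ifelse(short, code, substr(code, 1L, 3L))
}

#' Specify an index-diagnosis cohort
#'
#' Bundles the parameters that define the cohort: the index ICD-10 category
#' whose first occurrence marks disease onset, and the lookback /
#' follow-up windows (in days) over which pre-onset medical histories and
#' post-onset complications are collected. The study defaults are the first
#' F32 (major depressive disorder) claim with 2-year (730-day) windows on
#' both sides.
#'
#' @param index_code 3-character ICD-10 category defining onset.
#' @param pre_window_days,post_window_days Positive integer window lengths.
#' @param require_full_windows If `TRUE`, patients whose observed claim span
#'   does not cover both full windows around their index date are dropped.
#'   Default `FALSE`: no enrollment-span requirement is imposed, so the
#'   cohort size t counts every patient with an index claim.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(index_code = "F32", pre_window_days = 730L,
                        post_window_days = 730L, require_full_windows = FALSE) {
  index_code <- truncate_code(index_code)
  pre_window_days <- as.integer(pre_window_days)
  post_window_days <- as.integer(post_window_days)
  if (pre_window_days <= 0L || post_window_days <= 0L) {
    stop("window lengths must be positive", call. = FALSE)
  }
  structure(
    list(index_code = index_code, pre_window_days = pre_window_days,
         post_window_days = post_window_days,
         require_full_windows = isTRUE(require_full_windows)),
    class = "cohort_spec"
  )
}

#' Extract the index-diagnosis cohort as patient journeys
#'
#' A patient enters the cohort if their claims contain at least one record
#' whose 3-character category equals the index code; onset (the index date)
#' is the earliest such record. Each cohort member's journey holds two code
#' sets built from truncated categories:
#'
#' * `pre_codes`: categories claimed in `[index_date - pre_window_days,
#'   index_date)` — the pre-onset medical history;
#' * `post_codes`: categories claimed in `(index_date, index_date +
#'   post_window_days]` — the post-onset complications.
#'
#' Both windows exclude the index date itself, so same-day comorbid coding
#' is never attributed to either side, and the index category is excluded
#' from both sets. Multiplicity and within-window order are discarded: the
#' sets record only whether a category was ever claimed in the window.
#'
#' @param claims A claims tibble as returned by [read_claims()] or
#'   [generate_claims()].
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per cohort patient, sorted by
#'   `patient_id`: columns `patient_id`, `index_date`, and list-columns
#'   `pre_codes`, `post_codes` (character vectors, sorted). An empty cohort
#'   yields a zero-row tibble with a message, not an error.
#' @export
extract_cohort <- function(claims, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(claims) == 0L) stop("claims table is empty", call. = FALSE)
  claims <- dplyr::mutate(claims, category = suppressWarnings(truncate_code(.data$code)))

  idx <- claims[claims$category == spec$index_code, , drop = FALSE]
  if (nrow(idx) == 0L) {
    message("no patients carry index code ", spec$index_code, "; empty cohort")
    return(tibble::tibble(patient_id = character(), index_date = as.Date(character()),
                          pre_codes = list(), post_codes = list()))
  }
  index_dates <- stats::aggregate(idx$date, by = list(patient_id = idx$patient_id), FUN = min)
  names(index_dates)[2] <- "index_date"

  cohort_claims <- merge(claims, index_dates, by = "patient_id")
  off <- as.integer(cohort_claims$date - cohort_claims$index_date)
  not_index <- cohort_claims$category != spec$index_code
  in_pre <- not_index & off >= -spec$pre_window_days & off < 0L
  in_post <- not_index & off > 0L & off <= spec$post_window_days

  collect <- function(keep) {
    sub <- cohort_claims[keep, c("patient_id", "category")]
    split(sub$category, factor(sub$patient_id, levels = index_dates$patient_id))
  }
  pre_sets <- lapply(collect(in_pre), function(x) sort(unique(x)))
  post_sets <- lapply(collect(in_post), function(x) sort(unique(x)))

  journeys <- tibble::tibble(
    patient_id = index_dates$patient_id,
    index_date = index_dates$index_date,
    pre_codes = unname(pre_sets[index_dates$patient_id]),
    post_codes = unname(post_sets[index_dates$patient_id])
  )
  if (spec$require_full_windows) {
    span <- stats::aggregate(cohort_claims$date, by = list(patient_id = cohort_claims$patient_id),
                             FUN = range)
    span_min <- as.Date(span$x[, 1], origin = "1970-01-01")
    span_max <- as.Date(span$x[, 2], origin = "1970-01-01")
    keep_ids <- span$patient_id[
      span_min <= journeys$index_date[match(span$patient_id, journeys$patient_id)] - spec$pre_window_days &
      span_max >= journeys$index_date[match(span$patient_id, journeys$patient_id)] + spec$post_window_days
    ]
    journeys <- journeys[journeys$patient_id %in% keep_ids, , drop = FALSE]
  }
  journeys <- journeys[order(journeys$patient_id), , drop = FALSE]
  if (nrow(journeys) == 0L) message("cohort is empty after window filtering")
  journeys
}

#' Binarize cohort journeys into a patient-by-code indicator matrix
#'
#' Encodes the chosen window's code set of every cohort patient as a binary
#' patient-by-category matrix: entry `(p, x)` is 1 iff category `x` belongs
#' to patient `p`'s pre- (or post-) onset code set. Patients with an empty
#' code set keep an all-zero row, so the row count is always the cohort
#' size t that the rule indices are normalized by. Columns are the distinct
#' categories observed in that window, in lexicographic order.
#'
#' @param journeys A journeys tibble from [extract_cohort()].
#' @param window `"pre"` or `"post"`.
#' @return An integer 0/1 matrix with `rownames` = patient ids and
#'   `colnames` = sorted code categories.
#' @export
binarize <- function(journeys, window = c("pre", "post")) {
  window <- match.arg(window)
  if (nrow(journeys) == 0L) stop("no journeys to binarize", call. = FALSE)
  sets <- journeys[[paste0(window, "_codes")]]
  codes <- sort(unique(unlist(sets)))
  m <- matrix(0L, nrow = nrow(journeys), ncol = length(codes),
              dimnames = list(journeys$patient_id, codes))
  for (i in seq_along(sets)) {
    if (length(sets[[i]]) > 0L) m[i, sets[[i]]] <- 1L
  }
  m
}

#' Write a one-row-per-patient cohort summary
#'
#' @param journeys A journeys tibble from [extract_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(journeys, path) {
  out <- tibble::tibble(
    patient_id = journeys$patient_id,
    index_date = as.character(journeys$index_date),
    n_pre_codes = vapply(journeys$pre_codes, length, integer(1)),
    n_post_codes = vapply(journeys$post_codes, length, integer(1))
  )
  readr::write_csv(out, path)
  invisible(path)
}
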