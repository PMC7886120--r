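#' Define a planted pairwise association rule
#'
#' The synthetic generator plants dependence between two diagnosis
#' categories one pair at a time, mirroring the exclusively pairwise rules
#' the mining stage looks for. For each cohort patient the antecedent X is
#' drawn Bernoulli(`p_x`); the consequent Y is drawn Bernoulli(`conf`) when
#' X is present and Bernoulli(`p_y_base`) otherwise. The rule is planted in
#' the pre- or post-onset window.
#'
#' A post-window rule may be restricted to a pre-onset stratum via
#' `given_pre`: the planted conditional structure then applies only to
#' patients whose pre-onset code set contains every category in
#' `given_pre`; outside the stratum X and Y are drawn independently
#' (Bernoulli(`p_x`) and Bernoulli(`p_y_base`)). This emulates
#' complications whose association exists only within a medical-history
#' subgroup, the situation the stratified second stage is designed to
#' detect.
#'
#' @param x_code,y_code Distinct 3-character categories.
#' @param p_x Probability a patient has X in the window.
#' @param conf Probability of Y given X (the planted confidence).
#' @param p_y_base Probability of Y given not-X.
#' @param window `"pre"` or `"post"`.
#' @param given_pre Optional character vector of pre-onset categories
#'   defining the stratum in which the rule holds (post-window rules only).
#' @return An object of class `planted_rule`.
#' @export
planted_rule <- function(x_code, y_code, p_x, conf, p_y_base,
                         window = c("pre", "post"), given_pre = NULL) {
  window <- match.arg(window)
  x_code <- truncate_code(x_code); y_code <- truncate_code(y_code)
  if (x_code == y_code) stop("planted rule needs distinct codes", call. = FALSE)
  probs <- c(p_x = p_x, conf = conf, p_y_base = p_y_base)
  if (any(probs < 0 | probs > 1)) {
    stop("planted probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(given_pre)) {
    if (window != "post") stop("given_pre strata only apply to post-window rules", call. = FALSE)
    given_pre <- truncate_code(given_pre)
  }
  structure(list(x_code = x_code, y_code = y_code, p_x = p_x, conf = conf,
                 p_y_base = p_y_base, window = window, given_pre = given_pre),
            class = "planted_rule")
}

#' Configure the synthetic claims generator
#'
#' @param n_patients Number of cohort patients to simulate.
#' @param planted_rules List of [planted_rule()] objects.
#' @param background_codes Named numeric vector: independent per-patient
#'   probability of each background category appearing in a window.
#'   Background codes are drawn independently in both windows and must be
#'   disjoint from all planted codes.
#' @param index_code Index category every patient receives exactly once.
#' @param pre_window_days,post_window_days Window lengths in days.
#' @param index_date_range Two dates between which index dates are drawn
#'   uniformly.
#' @param claims_per_code Claims emitted per present code (default 1; set
#'   higher to exercise duplicate handling — duplicates collapse under set
#'   semantics).
#' @param seed Mandatory integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients, planted_rules = list(),
                             background_codes = numeric(),
                             index_code = "F32",
                             pre_window_days = 730L, post_window_days = 730L,
                             index_date_range = as.Date(c("2008-01-01", "2015-12-31")),
                             claims_per_code = 1L, seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic generation", call. = FALSE)
  if (n_patients < 1L) stop("n_patients must be positive", call. = FALSE)
  if (length(background_codes) > 0) {
    if (is.null(names(background_codes)) || any(!nzchar(names(background_codes)))) {
      stop("background_codes must be a named probability vector", call. = FALSE)
    }
    names(background_codes) <- truncate_code(names(background_codes))
    if (any(background_codes < 0 | background_codes > 1)) {
      stop("background probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  planted_codes <- unlist(lapply(planted_rules, function(r) c(r$x_code, r$y_code)))
  if (any(names(background_codes) %in% planted_codes)) {
    stop("background codes must be disjoint from planted codes", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), planted_rules = planted_rules,
         background_codes = background_codes, index_code = truncate_code(index_code),
         pre_window_days = as.integer(pre_window_days),
         post_window_days = as.integer(post_window_days),
         index_date_range = as.Date(index_date_range),
         claims_per_code = as.integer(claims_per_code), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# uniform random claim date(s) strictly inside a patient's window:
# offsets 1..window_days days before (pre) or after (post) the index date
.window_date <- function(index_date, window, window_days, k) {
  off <- sample.int(window_days, k, replace = TRUE)
  if (window == "pre") index_date - off else index_date + off
}

#' Generate a synthetic claims table with planted rule structure
#'
#' Every patient receives exactly one index-code claim at an index date
#' drawn uniformly from the configured calendar range. Planted rules and
#' background codes then decide which categories each patient carries in
#' each window (see [planted_rule()] for the dependence model); every
#' present category is emitted as `claims_per_code` claims at uniformly
#' random dates strictly inside its window. Patients therefore all survive
#' cohort extraction with `require_full_windows = FALSE`, and the
#' contingency counts of a planted pair concentrate around the closed-form
#' values of [expected_indices()].
#'
#' Post-window rules carrying a `given_pre` stratum are drawn after all
#' pre-window codes are assigned, so the stratum membership they condition
#' on is the same one [stratified_rules()] will condition on.
#'
#' @param config A [synthetic_config()].
#' @return A claims tibble (`patient_id`, `code`, `date`) in the same
#'   shape [read_claims()] produces, with rows in generation order.
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .generate_claims_impl(config))
}

.generate_claims_impl <- function(config) {
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  span <- as.integer(config$index_date_range[2] - config$index_date_range[1])
  index_dates <- config$index_date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L

  # membership[[window]][[code]] = logical vector over patients
  member <- list(pre = list(), post = list())
  add_code <- function(window, code, present) {
    prev <- member[[window]][[code]]
    if (is.null(prev)) prev <- logical(n)
    member[[window]][[code]] <<- prev | present
  }

  pre_rules <- Filter(function(r) r$window == "pre", config$planted_rules)
  post_rules <- Filter(function(r) r$window == "post", config$planted_rules)

  draw_rule <- function(r, in_stratum = NULL) {
    x <- stats::runif(n) < r$p_x
    p_y <- ifelse(x, r$conf, r$p_y_base)
    if (!is.null(in_stratum)) p_y <- ifelse(in_stratum, p_y, r$p_y_base)
    y <- stats::runif(n) < p_y
    list(x = x, y = y)
  }

  for (r in pre_rules) {
    d <- draw_rule(r)
    add_code("pre", r$x_code, d$x); add_code("pre", r$y_code, d$y)
  }
  for (code in names(config$background_codes)) {
    p <- config$background_codes[[code]]
    add_code("pre", code, stats::runif(n) < p)
    add_code("post", code, stats::runif(n) < p)
  }
  for (r in post_rules) {
    in_stratum <- NULL
    if (!is.null(r$given_pre)) {
      in_stratum <- rep(TRUE, n)
      for (code in r$given_pre) {
        pres <- member$pre[[code]]
        if (is.null(pres)) pres <- logical(n)
        in_stratum <- in_stratum & pres
      }
    }
    d <- draw_rule(r, in_stratum)
    add_code("post", r$x_code, d$x); add_code("post", r$y_code, d$y)
  }

  rows <- list(tibble::tibble(patient_id = ids, code = config$index_code,
                              date = index_dates))
  for (window in c("pre", "post")) {
    wdays <- if (window == "pre") config$pre_window_days else config$post_window_days
    for (code in names(member[[window]])) {
      who <- which(member[[window]][[code]])
      if (length(who) == 0L) next
      who <- rep(who, each = config$claims_per_code)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = ids[who], code = code,
        date = .window_date(index_dates[who], window, wdays, length(who))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Population values of support, confidence and lift for a planted rule
#'
#' Closed form implied by the index definitions: the fraction of patients
#' with both X and Y is `p_x * conf`, the confidence is `conf` by
#' construction, and the overall consequent frequency is
#' `P(Y) = p_x * conf + (1 - p_x) * p_y_base`, so lift is `conf / P(Y)`.
#' Mined indices on generated data converge to these values as the cohort
#' grows.
#'
#' @param rule A [planted_rule()].
#' @return A list with elements `support`, `confidence`, `lift`. When Y is
#'   impossible (`P(Y) = 0`) lift is `NA` with a warning.
#' @examples
#' expected_indices(planted_rule("G47", "K29", p_x = 0.4, conf = 0.7,
#'                               p_y_base = 0.2))
#' @export
expected_indices <- function(rule) {
  stopifnot(inherits(rule, "planted_rule"))
  p_y <- rule$p_x * rule$conf + (1 - rule$p_x) * rule$p_y_base
  lift <- if (p_y == 0) {
    warning("consequent has probability 0; lift undefined", call. = FALSE)
    NA_real_
  } else {
    rule$conf / p_y
  }
  list(support = rule$p_x * rule$conf, confidence = rule$conf, lift = lift)
}

#' Write synthetic claims alongside their ground truth
#'
#' Emits the generated claims as CSV and, next to it, a JSON file recording
#' each planted rule with its population indices — the ground truth a
#' mining run on the CSV should approximately recover.
#'
#' @param config A [synthetic_config()].
#' @param claims_path Output CSV path; the ground-truth JSON is written to
#'   the same path with extension `.truth.json`.
#' @return Invisibly, a list with the claims tibble and truth list.
#' @export
write_synthetic_claims <- function(config, claims_path) {
  claims <- generate_claims(config)
  readr::write_csv(claims, claims_path)
  truth <- lapply(config$planted_rules, function(r) {
    c(list(x_code = r$x_code, y_code = r$y_code, window = r$window,
           p_x = r$p_x, conf = r$conf, p_y_base = r$p_y_base,
           given_pre = r$given_pre),
      expected = list(expected_indices(r)))
  })
  truth_path <- sub("\\.csv$", ".truth.json", claims_path)
  if (identical(truth_path, claims_path)) truth_path <- paste0(claims_path, ".truth.json")
  jsonlite::write_json(list(n_patients = config$n_patients, seed = config$seed,
                            planted_rules = truth),
                       truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(claims = claims, truth = truth))
}
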