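#' Contingency table for an ordered pair of diagnosis categories
#'
#' Counts the four cells of the 2x2 table over all t cohort patients:
#' `a` with both X and Y, `b` with X only, `c` with Y only, `d` with
#' neither. All rule indices derive from these counts.
#'
#' @param matrix Binary patient-by-code matrix from [binarize()].
#' @param x,y Distinct column names (code categories).
#' @return A list with integer elements `a`, `b`, `c`, `d`, `t`
#'   (`a + b + c + d == t`).
#' @export
contingency <- function(matrix, x, y) {
  if (identical(x, y)) stop("x and y must be distinct codes", call. = FALSE)
  for (code in c(x, y)) {
    if (!code %in% colnames(matrix)) {
      stop("code '", code, "' is not a column of the matrix", call. = FALSE)
    }
  }
  cx <- matrix[, x] == 1L
  cy <- matrix[, y] == 1L
  a <- sum(cx & cy); b <- sum(cx & !cy); cc <- sum(!cx & cy)
  t <- nrow(matrix)
  list(a = a, b = b, c = cc, d = t - a - b - cc, t = t)
}

#' Support, confidence and lift from a contingency table
#'
#' Implements the standard market-basket indices on the 2x2 counts:
#' support `a/t`, confidence `a/(a+b)`, and lift
#' `{a/(a+b)} / {(a+c)/t}` — confidence divided by the consequent's
#' overall frequency, equal to 1 under independence. Confidence is
#' undefined (`NA`) when the antecedent never occurs (`a+b = 0`); lift is
#' additionally undefined when the consequent never occurs (`a+c = 0`).
#'
#' @param ct A contingency list from [contingency()], or any list with
#'   fields `a`, `b`, `c`, `t`.
#' @return A list with elements `support`, `confidence`, `lift`.
#' @examples
#' rule_indices(list(a = 3, b = 2, c = 2, d = 3, t = 10))
#' @export
rule_indices <- function(ct) {
  if (ct$t <= 0) stop("cohort size t must be positive", call. = FALSE)
  support <- ct$a / ct$t
  confidence <- if (ct$a + ct$b == 0) NA_real_ else ct$a / (ct$a + ct$b)
  p_y <- (ct$a + ct$c) / ct$t
  lift <- if (is.na(confidence) || p_y == 0) NA_real_ else confidence / p_y
  list(support = support, confidence = confidence, lift = lift)
}

#' Frequent unordered code pairs (Apriori)
#'
#' Returns every unordered pair of categories whose joint patient count is
#' at least `min_count`. The Apriori pruning step restricts the candidate
#' pairs to codes that are individually frequent (a pair can never be more
#' frequent than either member), after which joint counts are taken with a
#' single cross-product of the pruned indicator matrix. The result equals
#' exhaustive enumeration over all pairs.
#'
#' @param matrix Binary patient-by-code matrix.
#' @param min_count Minimum joint count (>= 1).
#' @return A tibble with columns `x_code`, `y_code` (`x_code < y_code`
#'   lexicographically) and `count`, sorted by count descending then codes.
#' @export
frequent_pairs <- function(matrix, min_count = 1L) {
  min_count <- as.integer(min_count)
  if (min_count < 1L) stop("min_count must be >= 1", call. = FALSE)
  empty <- tibble::tibble(x_code = character(), y_code = character(),
                          count = integer())
  if (ncol(matrix) < 2L) return(empty)
  singles <- colSums(matrix)
  keep <- names(singles)[singles >= min_count]  # Apriori pruning
  if (length(keep) < 2L) return(empty)
  sub <- matrix[, sort(keep), drop = FALSE]
  joint <- crossprod(sub)                       # joint counts for kept codes
  ij <- which(upper.tri(joint) & joint >= min_count, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(empty)
  out <- tibble::tibble(
    x_code = rownames(joint)[ij[, 1]],
    y_code = colnames(joint)[ij[, 2]],
    count = as.integer(joint[ij])
  )
  out[order(-out$count, out$x_code, out$y_code), ]
}

#' Configure rule filtering
#'
#' @param min_pair_count Minimum joint count `a` for a pair to be kept.
#'   The study default 51 drops pairs with 50 or fewer co-occurrences as
#'   infrequent.
#' @param min_confidence Minimum confidence for a directed rule (study
#'   default 0.5).
#' @param top_k Optional cap on the number of reported rules after sorting
#'   (the study tables report the top 10 by support).
#' @return An object of class `rule_filter`.
#' @export
rule_filter <- function(min_pair_count = 51L, min_confidence = 0.5,
                        top_k = NULL) {
  min_pair_count <- as.integer(min_pair_count)
  if (min_pair_count < 0L) stop("min_pair_count must be >= 0", call. = FALSE)
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(top_k)) top_k <- as.integer(top_k)
  structure(list(min_pair_count = min_pair_count,
                 min_confidence = min_confidence, top_k = top_k),
            class = "rule_filter")
}

#' Mine directed pairwise association rules
#'
#' For every frequent unordered pair, both directed rules X -> Y and
#' Y -> X are evaluated (the two share support but generally differ in
#' confidence and lift). A directed rule is kept iff its joint count
#' satisfies `min_pair_count` and its confidence reaches `min_confidence`.
#' Rules with undefined confidence or lift (zero denominators) are never
#' emitted. The result is sorted by support descending, ties broken by
#' confidence descending then `(x_code, y_code)` lexicographically, and
#' truncated to `top_k` when set.
#'
#' @param matrix Binary patient-by-code matrix; its row count is the
#'   cohort size t the indices are normalized by.
#' @param filt A [rule_filter()].
#' @return A tibble with columns `x_code` (antecedent), `y_code`
#'   (consequent), `count_a`, `support`, `confidence`, `lift`, carrying the
#'   cohort size in `attr(, "t")`.
#' @export
mine_rules <- function(matrix, filt = rule_filter()) {
  stopifnot(inherits(filt, "rule_filter"))
  t <- nrow(matrix)
  if (t == 0L) stop("matrix has no patients (t = 0)", call. = FALSE)
  pairs <- frequent_pairs(matrix, max(1L, filt$min_pair_count))
  empty <- tibble::tibble(x_code = character(), y_code = character(),
                          count_a = integer(), support = double(),
                          confidence = double(), lift = double())
  if (nrow(pairs) == 0L) {
    attr(empty, "t") <- t
    return(empty)
  }
  rows <- vector("list", 2L * nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ct <- contingency(matrix, pairs$x_code[i], pairs$y_code[i])
    fwd <- rule_indices(ct)
    rev <- rule_indices(list(a = ct$a, b = ct$c, c = ct$b, d = ct$d, t = ct$t))
    rows[[2L * i - 1L]] <- tibble::tibble(
      x_code = pairs$x_code[i], y_code = pairs$y_code[i], count_a = ct$a,
      support = fwd$support, confidence = fwd$confidence, lift = fwd$lift)
    rows[[2L * i]] <- tibble::tibble(
      x_code = pairs$y_code[i], y_code = pairs$x_code[i], count_a = ct$a,
      support = rev$support, confidence = rev$confidence, lift = rev$lift)
  }
  rules <- dplyr::bind_rows(rows)
  rules <- rules[!is.na(rules$confidence) & !is.na(rules$lift) &
                 rules$count_a >= filt$min_pair_count &
                 rules$confidence >= filt$min_confidence, , drop = FALSE]
  rules <- rules[order(-rules$support, -rules$confidence, rules$x_code,
                       rules$y_code), , drop = FALSE]
  if (!is.null(filt$top_k)) rules <- utils::head(rules, filt$top_k)
  attr(rules, "t") <- t
  rules
}

#' Second-stage rule mining within a pre-onset stratum
#'
#' Restricts the cohort to the patients whose pre-onset code set contains
#' both categories of the antecedent pair (the stratum size equals the
#' contingency `a` of that pair on the pre-onset matrix), then mines
#' post-onset complication rules inside the stratum with the stratum size
#' as cohort size t. Associations that exist only within a
#' medical-history subgroup surface here with their within-stratum
#' confidence, which the unstratified analysis dilutes.
#'
#' @param journeys Journeys tibble from [extract_cohort()].
#' @param antecedent Character vector of two distinct pre-onset categories.
#' @param filt A [rule_filter()] applied to the post-onset rules.
#' @return A list with `subset_size` (integer) and `rules` (tibble as in
#'   [mine_rules()]). An antecedent pair absent from the data yields
#'   `subset_size = 0` and an empty rule tibble, with a message.
#' @export
stratified_rules <- function(journeys, antecedent, filt = rule_filter()) {
  antecedent <- truncate_code(antecedent)
  if (length(antecedent) != 2L || antecedent[1] == antecedent[2]) {
    stop("antecedent must be two distinct codes", call. = FALSE)
  }
  in_stratum <- vapply(journeys$pre_codes,
                       function(s) all(antecedent %in% s), logical(1))
  subset <- journeys[in_stratum, , drop = FALSE]
  if (nrow(subset) == 0L) {
    message("antecedent pair {", paste(antecedent, collapse = ", "),
            "} occurs in no patient; empty stratum")
    empty <- tibble::tibble(x_code = character(), y_code = character(),
                            count_a = integer(), support = double(),
                            confidence = double(), lift = double())
    attr(empty, "t") <- 0L
    return(list(subset_size = 0L, rules = empty))
  }
  rules <- mine_rules(binarize(subset, "post"), filt)
  list(subset_size = nrow(subset), rules = rules)
}

#' Write a rule table as CSV
#'
#' Writes one row per rule with presentation columns rounded to one
#' decimal in percent (support, confidence) or ratio (lift) scale — the
#' conventional layout of published rule tables — alongside full-precision
#' machine-readable columns (`support`, `confidence`, `lift`, `count_a`)
#' that round-trip exactly.
#'
#' @param rules Rule tibble from [mine_rules()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(rules, path) {
  out <- tibble::tibble(
    rule_index = seq_len(nrow(rules)),
    antecedent = rules$x_code,
    consequent = rules$y_code,
    support_pct = sprintf("%.1f", 100 * rules$support),
    confidence_pct = sprintf("%.1f", 100 * rules$confidence),
    lift_1dp = sprintf("%.1f", rules$lift),
    count_a = rules$count_a,
    support = rules$support,
    confidence = rules$confidence,
    lift = rules$lift
  )
  readr::write_csv(out, path)
  invisible(path)
}
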