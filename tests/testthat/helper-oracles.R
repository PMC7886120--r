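# Independent oracles and fixture builders shared across test files.

# Exhaustive double-loop rule miner: every directed pair, no Apriori
# pruning, no shortcuts. The reference mine_rules is checked against.
brute_force_rules <- function(m, min_pair_count, min_confidence) {
  t <- nrow(m)
  codes <- colnames(m)
  rows <- list()
  for (x in codes) {
    for (y in codes) {
      if (x == y) next
      a <- sum(m[, x] == 1L & m[, y] == 1L)
      b <- sum(m[, x] == 1L & m[, y] == 0L)
      cc <- sum(m[, x] == 0L & m[, y] == 1L)
      if (a < max(1L, min_pair_count)) next
      conf <- a / (a + b)
      if (conf < min_confidence) next
      rows[[length(rows) + 1L]] <- data.frame(
        x_code = x, y_code = y, count_a = a, support = a / t,
        confidence = conf, lift = conf / ((a + cc) / t),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(x_code = character(), y_code = character(),
                      count_a = integer(), support = double(),
                      confidence = double(), lift = double()))
  }
  out <- do.call(rbind, rows)
  out[order(out$x_code, out$y_code), , drop = FALSE]
}

# Random binary patient-by-code matrix with lexicographic column names.
random_item_matrix <- function(n_patients, n_codes, p = 0.3) {
  codes <- sprintf("C%02d", seq_len(n_codes))
  m <- matrix(as.integer(stats::runif(n_patients * n_codes) < p),
              nrow = n_patients,
              dimnames = list(sprintf("p%03d", seq_len(n_patients)), codes))
  m
}

# Build an indicator matrix from explicit member row lists.
matrix_from_members <- function(n, members) {
  codes <- sort(names(members))
  m <- matrix(0L, nrow = n, ncol = length(codes),
              dimnames = list(sprintf("p%03d", seq_len(n)), codes))
  for (code in codes) m[members[[code]], code] <- 1L
  m
}

# Canonical ordering for rule-table comparison.
sort_rules <- function(r) {
  r <- as.data.frame(r)[, c("x_code", "y_code", "count_a", "support",
                            "confidence", "lift")]
  r <- r[order(r$x_code, r$y_code), , drop = FALSE]
  rownames(r) <- NULL
  r
}

# Tiny claims tibble from a (patient, code, date-string) triple table.
claims_from_triples <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, character(1), 1),
    code = vapply(rows, `[[`, character(1), 2),
    date = as.Date(vapply(rows, `[[`, character(1), 3))
  )
}
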