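# Shared fixture builders and the independent brute-force episode
# partitioner used as the grouping oracle.

make_claims <- function(dates, codes, person = "W1", family = "F1",
                        version = 10L, record_type = "mother") {
  data.table::data.table(
    person_id = person, family_id = family,
    service_date = as.Date(dates), icd_version = as.integer(version),
    code = codes, record_type = record_type)
}

make_enrollment <- function(person = "W1", family = "F1",
                            start = "2014-01-01", end = "2022-01-01",
                            birth_year = 1990L, sex = "F",
                            race = "White", state = "TX") {
  data.table::data.table(
    person_id = person, family_id = family,
    span_start = as.Date(start), span_end = as.Date(end),
    birth_year = as.integer(birth_year), sex = sex,
    race_ethnicity = race, state = state,
    aso = "no", cdhp = "none", health_exchange = "no", product = "POS")
}

# outcome-evidence type codes used by the oracle: 0 none, 1 live birth,
# 2 stillbirth, 3 spontaneous abortion, 4 induced abortion
.type_code <- c("Z34.91", "O80", "Z37.1", "O03.9", "O04.89")

claims_from_types <- function(days, types, origin = as.Date("2017-01-01")) {
  make_claims(origin + days, .type_code[types + 1L])
}

# scan one contiguous segment under the gap rules; TRUE iff no split fires
segment_valid <- function(days, types, gap_live = 120L, gap_loss = 42L,
                          max_span = 308L) {
  out_type <- 0L; out_day <- NA_integer_; start <- days[1]
  for (i in seq_along(days)) {
    if (i > 1L) {
      if (out_type > 0L) {
        gap <- if (out_type == 1L) gap_live else gap_loss
        if (days[i] - out_day >= gap) return(FALSE)
      } else if (days[i] - start > max_span) {
        return(FALSE)
      }
    }
    if (types[i] > 0L) { out_type <- types[i]; out_day <- days[i] }
  }
  TRUE
}

# exhaustive partitioner: enumerate every contiguous partition, keep the
# gap-consistent ones, and return the greedy-earliest one (lexicographically
# longest blocks from the left)
brute_force_partition <- function(days, types, gap_live = 120L,
                                  gap_loss = 42L, max_span = 308L) {
  n <- length(days)
  if (n == 0L) return(integer(0))
  valid <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      valid[i, j] <- segment_valid(days[i:j], types[i:j],
                                   gap_live, gap_loss, max_span)
    }
  }
  lex_greater <- function(a, b) {
    for (i in seq_len(min(length(a), length(b)))) {
      if (a[i] != b[i]) return(a[i] > b[i])
    }
    length(a) < length(b)
  }
  best <- NULL
  n_masks <- if (n == 1L) 1L else 2L^(n - 1L)
  for (mask in 0:(n_masks - 1L)) {
    cuts <- if (n > 1L) which(bitwAnd(mask, 2L^(0:(n - 2L))) > 0L) else integer(0)
    starts <- c(1L, cuts + 1L); ends <- c(cuts, n)
    if (all(valid[cbind(starts, ends)])) {
      lens <- ends - starts + 1L
      if (is.null(best) || lex_greater(lens, best)) best <- lens
    }
  }
  rep(seq_along(best), best)
}

random_grouping_case <- function() {
  n <- sample(1:12, 1L)
  days <- sort(sample(0:600, n, replace = TRUE))
  types <- sample(0:4, n, replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  list(days = days, types = types)
}
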