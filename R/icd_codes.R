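# ICD-9/10-CM diagnosis-code classifiers. All classification is table-driven:
# the mapping tables live under inst/extdata as delimited text so that users
# can audit and extend them. Tables are loaded once per session and validated.

.icd10_rx <- "^[A-Z][0-9][0-9A-Z](\\.[0-9A-Z]{1,4})?$"
.icd9_rx  <- "^([0-9]{3}(\\.[0-9]{1,2})?|V[0-9]{2}(\\.[0-9]{1,2})?|E[0-9]{3}(\\.[0-9])?)$"

#' Load the shipped ICD mapping tables
#'
#' Reads the delimited mapping tables shipped with the package (exposure
#' family rules, ICD-9 to ICD-10 sleep-code conversions, maternal and birth
#' outcome codes, ICD-9 gestational-week codes, state-to-census-division
#' lookup), validates every code against the ICD-CM lexical patterns, and
#' caches them for the session.
#'
#' @param refresh re-read the tables from disk even if already cached.
#' @return A named list of data.tables, invisibly.
#' @export
load_code_maps <- function(refresh = FALSE) {
  if (!refresh && !is.null(.perisleep_env$maps)) {
    return(invisible(.perisleep_env$maps))
  }
  pth <- function(f) system.file("extdata", f, package = "perisleep", mustWork = TRUE)
  rd <- function(f) data.table::as.data.table(
    read.delim(pth(f), stringsAsFactors = FALSE, colClasses = "character")
  )
  maps <- list(
    exposure = rd("exposure_code_rules.tsv"),
    icd9_map = rd("icd9_sleep_map.tsv"),
    maternal = rd("maternal_outcome_codes.tsv"),
    birth    = rd("birth_outcome_codes.tsv"),
    ga9      = rd("icd9_ga_weeks.tsv"),
    division = rd("census_divisions.tsv")
  )
  maps$ga9$weeks <- as.integer(maps$ga9$weeks)
  stopifnot(
    all(grepl(.icd9_rx, maps$icd9_map$icd9)),
    all(grepl(.icd10_rx, maps$icd9_map$icd10)),
    all(grepl(.icd9_rx, maps$ga9$code)),
    all(maps$ga9$weeks >= 1 & maps$ga9$weeks <= 42),
    all(maps$exposure$family %in% c("F51", "G25", "G47", "R06")),
    all(maps$exposure$match %in% c("prefix", "exact")),
    !anyDuplicated(maps$icd9_map$icd9),
    !anyDuplicated(maps$division$state)
  )
  # round-trip consistency: every ICD-9 sleep code must convert to an ICD-10
  # code that itself classifies into one of the four exposure families
  fam <- match_code_rules(maps$icd9_map$icd10, maps$exposure, "family")
  stopifnot(!anyNA(fam))
  .perisleep_env$maps <- maps
  invisible(maps)
}

#' Normalize an ICD code to dotted canonical form
#'
#' Trims whitespace, upper-cases, and inserts the dot after the category
#' characters (position 3 for both ICD-9-CM numeric codes and ICD-10-CM)
#' when the input is undotted. Lexically invalid codes are an error.
#'
#' @param code character vector of ICD codes, dotted or undotted.
#' @param icd_version integer vector (9 or 10), recycled.
#' @return Character vector of dotted canonical codes.
#' @export
normalize_icd <- function(code, icd_version = 10L) {
  code <- toupper(trimws(as.character(code)))
  if (any(!nzchar(code) | is.na(code))) {
    stop("empty or missing ICD code")
  }
  undotted <- !grepl(".", code, fixed = TRUE) & nchar(code) > 3L
  code[undotted] <- paste0(
    substr(code[undotted], 1L, 3L), ".",
    substring(code[undotted], 4L)
  )
  icd_version <- rep_len(as.integer(icd_version), length(code))
  bad <- ifelse(icd_version == 9L, !grepl(.icd9_rx, code), !grepl(.icd10_rx, code))
  if (any(bad)) {
    stop("malformed ICD-", icd_version[which(bad)[1]], " code: '",
         code[which(bad)[1]], "'")
  }
  code
}

# vectorized rule matcher: exact rules win over prefix rules; longer
# prefixes win over shorter ones. `codes` must already be normalized.
match_code_rules <- function(codes, rules, value_col) {
  out <- rep(NA_character_, length(codes))
  pref <- rules[rules$match == "prefix", ]
  if (nrow(pref)) {
    for (i in order(nchar(pref$pattern))) {
      hit <- startsWith(codes, pref$pattern[i])
      out[hit] <- pref[[value_col]][i]
    }
  }
  ex <- rules[rules$match == "exact", ]
  if (nrow(ex)) {
    m <- match(codes, ex$pattern)
    out[!is.na(m)] <- ex[[value_col]][m[!is.na(m)]]
  }
  out
}

#' Convert ICD-9-CM sleep codes to ICD-10-CM equivalents
#'
#' Applies the shipped family-level conversion table (307.4x to F51.*,
#' 780.5x to G47.*, 786.0x to R06.*, 327.23 to G47.33, 333.94 to G25.81).
#' Codes without a conversion entry are returned unchanged so that
#' downstream classifiers simply ignore them.
#'
#' @param code character vector of ICD-9-CM codes.
#' @return Character vector of ICD-10-CM codes (or the input where unmapped).
#' @export
convert_icd9_sleep <- function(code) {
  maps <- load_code_maps()
  code <- normalize_icd(code, 9L)
  m <- match(code, maps$icd9_map$icd9)
  ifelse(is.na(m), code, maps$icd9_map$icd10[m])
}

#' Classify a diagnosis code into a sleep-disorder exposure family
#'
#' Returns the exposure family for codes that qualify as sleep disorders or
#' breathing abnormalities: any F51.*, G25.81 only, any G47.*, any R06.*.
#' ICD-9 codes are first converted with [convert_icd9_sleep()], so an ICD-9
#' code qualifies exactly when its ICD-10 image does (e.g. 327.23 maps to
#' G47.33 and classifies as G47).
#'
#' @param code character vector of ICD codes.
#' @param icd_version 9 or 10 (recycled).
#' @return Character vector: "F51", "G25", "G47", "R06", or `NA` for
#'   non-qualifying codes.
#' @export
classify_exposure_code <- function(code, icd_version = 10L) {
  maps <- load_code_maps()
  icd_version <- rep_len(as.integer(icd_version), length(code))
  if (!all(icd_version %in% c(9L, 10L))) stop("icd_version must be 9 or 10")
  code <- normalize_icd(code, icd_version)
  is9 <- icd_version == 9L
  if (any(is9)) code[is9] <- convert_icd9_sleep(code[is9])
  # ICD-9 codes whose conversion left them unchanged can never match the
  # ICD-10 rules (different lexical space), so this is safe in one pass
  match_code_rules(code, maps$exposure, "family")
}

#' Classify an ICD-10-CM code as a maternal outcome
#'
#' @param code character vector of ICD-10-CM codes.
#' @return Character vector with one of "cesarean", "gestational_diabetes",
#'   "gestational_hypertension", "preeclampsia", "postpartum_depression",
#'   "stillbirth", or `NA`.
#' @export
classify_maternal_outcome_code <- function(code) {
  maps <- load_code_maps()
  match_code_rules(normalize_icd(code, 10L), maps$maternal, "outcome")
}

#' Classify an ICD-10-CM code from an infant record as a birth outcome
#'
#' @param code character vector of ICD-10-CM codes.
#' @return data.table with columns `axis` ("size_for_ga", "birthweight",
#'   "gestation_period") and `level` ("SGA", "LGA", "LBW", "HBW",
#'   "preterm", "post_term"), `NA` where the code is not a birth-outcome code.
#' @export
classify_birth_outcome_code <- function(code) {
  maps <- load_code_maps()
  code <- normalize_icd(code, 10L)
  data.table::data.table(
    code = code,
    axis = match_code_rules(code, maps$birth, "axis"),
    level = match_code_rules(code, maps$birth, "level")
  )
}

#' Extract gestational weeks from a weeks-of-gestation code
#'
#' ICD-10-CM Z3A.NN codes carry the completed week directly (Z3A.00 and
#' Z3A.01, unspecified and under-8 weeks, carry none). ICD-9-CM 765.2x
#' subcodes document week ranges; the shipped table maps each subcode to its
#' midpoint week, rounded up. Weeks outside 1-42 return `NA` with a warning.
#'
#' @param code character vector of ICD codes.
#' @param icd_version 9 or 10 (recycled).
#' @return Integer vector of completed weeks, `NA` where not a week code.
#' @export
gestational_week_from_code <- function(code, icd_version = 10L) {
  maps <- load_code_maps()
  icd_version <- rep_len(as.integer(icd_version), length(code))
  code <- normalize_icd(code, icd_version)
  out <- rep(NA_integer_, length(code))
  i10 <- icd_version == 10L & startsWith(code, "Z3A.")
  if (any(i10)) {
    wk <- suppressWarnings(as.integer(substring(code[i10], 5L)))
    wk[wk %in% c(0L, 1L)] <- NA_integer_  # Z3A.00 / Z3A.01 carry no week
    if (any(!is.na(wk) & (wk < 1L | wk > 42L))) {
      warning("weeks-of-gestation code outside 1-42 treated as missing")
      wk[!is.na(wk) & (wk < 1L | wk > 42L)] <- NA_integer_
    }
    out[i10] <- wk
  }
  i9 <- icd_version == 9L
  if (any(i9)) {
    m <- match(code[i9], maps$ga9$code)
    out[i9] <- maps$ga9$weeks[m]
  }
  out
}

#' Map a US state code to its census division
#'
#' Uses the standard US Census Bureau nine-division grouping of the 50
#' states plus DC. Unknown state codes map to `NA`.
#'
#' @param state character vector of two-letter state codes.
#' @return Character vector of division names.
#' @export
census_division <- function(state) {
  maps <- load_code_maps()
  maps$division$division[match(toupper(as.character(state)), maps$division$state)]
}

# pregnancy-related claim membership used by the episode builder: the
# obstetric O chapter, weeks-of-gestation and delivery-outcome Z codes,
# pregnancy supervision codes, and their ICD-9 counterparts.
is_pregnancy_code <- function(code, icd_version = 10L) {
  icd_version <- rep_len(as.integer(icd_version), length(code))
  code <- normalize_icd(code, icd_version)
  out <- logical(length(code))
  i10 <- icd_version == 10L
  out[i10] <- startsWith(code[i10], "O") |
    startsWith(code[i10], "Z3A") | startsWith(code[i10], "Z33") |
    startsWith(code[i10], "Z34") | startsWith(code[i10], "Z37") |
    startsWith(code[i10], "Z38")
  i9 <- icd_version == 9L
  if (any(i9)) {
    c9 <- code[i9]
    num <- suppressWarnings(as.integer(substr(c9, 1L, 3L)))
    out[i9] <- (!is.na(num) & num >= 630L & num <= 679L) |
      startsWith(c9, "V22") | startsWith(c9, "V23") |
      startsWith(c9, "V27") | startsWith(c9, "765.2")
  }
  out
}

# episode outcome-record evidence (ICD-10; mother records)
classify_outcome_evidence <- function(code, icd_version = 10L) {
  code <- normalize_icd(code, rep_len(as.integer(icd_version), length(code)))
  out <- rep(NA_character_, length(code))
  out[startsWith(code, "O03")] <- "spontaneous_abortion"
  out[startsWith(code, "O04")] <- "induced_abortion"
  out[code == "Z37.1" | startsWith(code, "P95")] <- "stillbirth"
  out[startsWith(code, "O80") | startsWith(code, "O82") | code == "Z37.0"] <- "live_birth"
  out
}
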