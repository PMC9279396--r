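#' Structured EHR data container
#'
#' An `ehr_data` object holds the three flat tables the screening pipeline
#' consumes, cross-validated against each other:
#' \describe{
#'   \item{patients}{`patient_id`, `gender` (one of `"female"`, `"male"`,
#'     `"unknown_other"`), `birth_date` (`Date`).}
#'   \item{encounters}{`encounter_id`, `patient_id`, `encounter_type` (one of
#'     `"emergency"`, `"inpatient"`, `"outpatient_other"`), `discharge_date`
#'     (`Date`).}
#'   \item{diagnoses}{`patient_id`, `encounter_id`, `code_system` (`"ICD9CM"`
#'     or `"ICD10CM"`), `code` (normalized: uppercase, dots stripped), plus
#'     the joined `discharge_date` and `encounter_type` of the carrying
#'     encounter.}
#' }
#'
#' @param patients,encounters,diagnoses data frames with the columns above
#'   (`birth_date`/`discharge_date` may be ISO-8601 strings; codes may carry
#'   dots — both are normalized on construction).
#' @return a validated `ehr_data` object.
#' @seealso [read_ehr_tables()], [write_ehr_tables()]
#' @export
ehr_data <- function(patients, encounters, diagnoses) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stopf("%s table is missing required column(s): %s",
            what, paste(miss, collapse = ", "))
    }
  }
  need(patients, c("patient_id", "gender", "birth_date"), "patients")
  need(encounters, c("encounter_id", "patient_id", "encounter_type",
                     "discharge_date"), "encounters")
  need(diagnoses, c("patient_id", "encounter_id", "code_system", "code"),
       "diagnoses")

  patients <- data.frame(
    patient_id = as.character(patients$patient_id),
    gender = normalize_gender(patients$gender),
    birth_date = parse_date_col(patients$birth_date, "patients", "birth_date"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(patients$patient_id)) {
    stopf("duplicate patient_id in patients table: %s",
          patients$patient_id[anyDuplicated(patients$patient_id)])
  }

  encounters <- data.frame(
    encounter_id = as.character(encounters$encounter_id),
    patient_id = as.character(encounters$patient_id),
    encounter_type = normalize_encounter_type(encounters$encounter_type),
    discharge_date = parse_date_col(encounters$discharge_date, "encounters",
                                    "discharge_date"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(encounters$encounter_id)) {
    stopf("duplicate encounter_id in encounters table")
  }
  unknown_pat <- setdiff(encounters$patient_id, patients$patient_id)
  if (length(unknown_pat)) {
    stopf("encounter references unknown patient_id: %s",
          paste(utils::head(unknown_pat, 5), collapse = ", "))
  }

  diagnoses <- data.frame(
    patient_id = as.character(diagnoses$patient_id),
    encounter_id = as.character(diagnoses$encounter_id),
    code_system = normalize_code_system(diagnoses$code_system),
    code = normalize_code(diagnoses$code),
    stringsAsFactors = FALSE
  )
  if (any(diagnoses$code == "")) {
    stopf("empty diagnosis code at diagnoses row %d", which(diagnoses$code == "")[1])
  }
  idx <- match(diagnoses$encounter_id, encounters$encounter_id)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stopf("diagnosis row %d (patient %s) references unknown encounter '%s'",
          bad, diagnoses$patient_id[bad], diagnoses$encounter_id[bad])
  }
  if (any(diagnoses$patient_id != encounters$patient_id[idx])) {
    bad <- which(diagnoses$patient_id != encounters$patient_id[idx])[1]
    stopf("diagnosis row %d: encounter '%s' belongs to a different patient",
          bad, diagnoses$encounter_id[bad])
  }
  diagnoses$discharge_date <- encounters$discharge_date[idx]
  diagnoses$encounter_type <- encounters$encounter_type[idx]

  # age sanity at every encounter
  bidx <- match(encounters$patient_id, patients$patient_id)
  ages <- age_at(patients$birth_date[bidx], encounters$discharge_date)
  if (any(ages < 0 | ages > 120)) {
    bad <- which(ages < 0 | ages > 120)[1]
    stopf("patient %s has implausible age %d at encounter %s",
          encounters$patient_id[bad], ages[bad], encounters$encounter_id[bad])
  }

  # canonical row order makes reads order-insensitive
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  encounters <- encounters[order(encounters$patient_id,
                                 encounters$discharge_date,
                                 encounters$encounter_id), , drop = FALSE]
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$encounter_id,
                               diagnoses$code_system, diagnoses$code), , drop = FALSE]
  rownames(patients) <- rownames(encounters) <- rownames(diagnoses) <- NULL

  structure(list(patients = patients, encounters = encounters,
                 diagnoses = diagnoses),
            class = "ehr_data")
}

normalize_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("f")] <- "female"
  x[x %in% c("m")] <- "male"
  bad <- !(x %in% c("female", "male", "unknown_other"))
  if (any(bad)) {
    warnf("%d patient(s) with unrecognized gender mapped to 'unknown_other'",
          sum(bad))
    x[bad] <- "unknown_other"
  }
  x
}

normalize_encounter_type <- function(x) {
  x <- tolower(trimws(as.character(x)))
  ok <- c("emergency", "inpatient", "outpatient_other")
  bad <- !(x %in% ok)
  if (any(bad)) {
    stopf("unknown encounter_type '%s' (expected one of %s)",
          x[bad][1], paste(ok, collapse = ", "))
  }
  x
}

normalize_code_system <- function(x) {
  x <- toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))
  bad <- !(x %in% c("ICD9CM", "ICD10CM"))
  if (any(bad)) stopf("unknown code_system '%s'", x[bad][1])
  x
}

parse_date_col <- function(x, table, col) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1]
    stopf("%s row %d: cannot parse %s '%s' as ISO-8601 date",
          table, bad, col, as.character(x)[bad])
  }
  d
}

#' @export
print.ehr_data <- function(x, ...) {
  cat(sprintf("ehr_data: %d patients, %d encounters, %d diagnosis events\n",
              nrow(x$patients), nrow(x$encounters), nrow(x$diagnoses)))
  if (nrow(x$encounters)) {
    cat(sprintf("  discharge dates %s .. %s\n",
                min(x$encounters$discharge_date),
                max(x$encounters$discharge_date)))
  }
  invisible(x)
}

#' Subset an EHR container to a set of patients
#'
#' @param x an `ehr_data` object.
#' @param i character vector of patient ids (all must exist).
#' @param ... ignored.
#' @return an `ehr_data` restricted to the given patients.
#' @export
`[.ehr_data` <- function(x, i, ...) {
  i <- as.character(i)
  miss <- setdiff(i, x$patients$patient_id)
  if (length(miss)) stopf("unknown patient id(s): %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  structure(list(
    patients = x$patients[x$patients$patient_id %in% i, , drop = FALSE],
    encounters = x$encounters[x$encounters$patient_id %in% i, , drop = FALSE],
    diagnoses = x$diagnoses[x$diagnoses$patient_id %in% i, , drop = FALSE]
  ), class = "ehr_data")
}

#' Read EHR flat tables
#'
#' Reads the three delimited interchange tables and assembles a validated
#' [ehr_data()] container.  Diagnosis codes are normalized (uppercase, dots
#' stripped) and joined to their encounters; a diagnosis referencing an
#' unknown encounter, a missing required column, or an unparseable date is an
#' error naming the offending column or row.
#'
#' @param patients_path CSV with columns `patient_id, gender, birth_date`.
#' @param encounters_path CSV with columns
#'   `encounter_id, patient_id, encounter_type, discharge_date`.
#' @param diagnoses_path CSV with columns
#'   `patient_id, encounter_id, code_system, code`.
#' @return an `ehr_data` object.
#' @export
read_ehr_tables <- function(patients_path, encounters_path, diagnoses_path) {
  rd <- function(p) {
    if (!file.exists(p)) stopf("file not found: %s", p)
    utils::read.csv(p, colClasses = "character", check.names = FALSE)
  }
  ehr_data(rd(patients_path), rd(encounters_path), rd(diagnoses_path))
}

#' Write EHR flat tables
#'
#' Inverse of [read_ehr_tables()]: writes `patients.csv`, `encounters.csv`
#' and `diagnoses.csv` under `dir`.  Reading them back yields an identical
#' container.
#'
#' @param ehr an `ehr_data` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_ehr_tables <- function(ehr, dir) {
  stopifnot(inherits(ehr, "ehr_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "encounters.csv", "diagnoses.csv"))
  utils::write.csv(ehr$patients, paths[1], row.names = FALSE)
  utils::write.csv(ehr$encounters, paths[2], row.names = FALSE)
  dx <- ehr$diagnoses[, c("patient_id", "encounter_id", "code_system", "code")]
  utils::write.csv(dx, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Completed age in years at a date
#'
#' @param birth_date,date `Date` vectors (recycled); `date` must not precede
#'   `birth_date`.
#' @return integer vector of completed years.
#' @export
#' @examples
#' age_at(as.Date("2000-06-15"), as.Date("2018-06-14"))  # 17
#' age_at(as.Date("2000-06-15"), as.Date("2018-06-15"))  # 18
age_at <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (any(date < birth_date)) stopf("date precedes birth_date")
  b <- as.POSIXlt(birth_date)
  d <- as.POSIXlt(date)
  age <- d$year - b$year
  before_birthday <- d$mon < b$mon | (d$mon == b$mon & d$mday < b$mday)
  as.integer(age - before_birthday)
}

#' Read a CCSR code-to-category mapping
#'
#' Each ICD-10-CM code maps to exactly one default CCSR category (for
#' example `"F329" -> "MBD002"`).  Codes are normalized on read.
#'
#' @param path CSV with columns `code, ccsr_category`.
#' @return a named character vector: `names()` are normalized codes, values
#'   are CCSR category codes.
#' @export
read_ccsr_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  miss <- setdiff(c("code", "ccsr_category"), names(df))
  if (length(miss)) stopf("ccsr map is missing column(s): %s",
                          paste(miss, collapse = ", "))
  code <- normalize_code(df$code)
  if (anyDuplicated(code)) {
    stopf("code '%s' maps to more than one CCSR category",
          code[anyDuplicated(code)][1])
  }
  stats::setNames(as.character(df$ccsr_category), code)
}

#' Read expert association ratings for diagnosis codes
#'
#' @param path CSV with columns `code, rating`; rating is one of
#'   `"positive"`, `"negative"`, `"unrelated"`, `"unsure"`.
#' @return a named character vector keyed by normalized code.
#' @export
read_association_ratings <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  miss <- setdiff(c("code", "rating"), names(df))
  if (length(miss)) stopf("association ratings missing column(s): %s",
                          paste(miss, collapse = ", "))
  rating <- tolower(trimws(df$rating))
  ok <- c("positive", "negative", "unrelated", "unsure")
  if (any(!rating %in% ok)) {
    stopf("unknown association rating '%s'", rating[!rating %in% ok][1])
  }
  code <- normalize_code(df$code)
  if (anyDuplicated(code)) stopf("code '%s' rated more than once",
                                 code[anyDuplicated(code)][1])
  stats::setNames(rating, code)
}
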