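# Fixture builders and independent oracles used across the suite.

# Compact ehr_data builder.  `enc` rows: id, type, date; `dx` rows:
# encounter id, code (ICD10CM unless prefixed "9:").
toy_ehr <- function(patients, enc, dx = NULL) {
  enc_df <- do.call(rbind, lapply(enc, function(e) {
    data.frame(encounter_id = e[[1]], patient_id = e[[2]],
               encounter_type = e[[3]], discharge_date = e[[4]],
               stringsAsFactors = FALSE)
  }))
  dx_df <- if (is.null(dx) || !length(dx)) {
    data.frame(patient_id = character(), encounter_id = character(),
               code_system = character(), code = character())
  } else {
    do.call(rbind, lapply(dx, function(d) {
      code <- d[[2]]
      sys <- if (startsWith(code, "9:")) "ICD9CM" else "ICD10CM"
      data.frame(
        patient_id = enc_df$patient_id[match(d[[1]], enc_df$encounter_id)],
        encounter_id = d[[1]], code_system = sys,
        code = sub("^9:", "", code), stringsAsFactors = FALSE)
    }))
  }
  pat_df <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p[[1]], gender = p[[2]], birth_date = p[[3]],
               stringsAsFactors = FALSE)
  }))
  ehr_data(pat_df, enc_df, dx_df)
}

# a patient with k dx-carrying encounters on distinct in-period dates
simple_patient_ehr <- function(id = "p1", k = 5, type = "outpatient_other",
                               code = "F329", gender = "female",
                               birth = "1985-01-01") {
  dates <- as.character(as.Date("2016-01-01") + seq_len(k) * 30)
  enc <- lapply(seq_len(k), function(i) {
    list(paste0(id, "-e", i), id, type, dates[i])
  })
  dx <- lapply(seq_len(k), function(i) list(paste0(id, "-e", i), code))
  toy_ehr(list(list(id, gender, birth)), enc, dx)
}

toy_ccsr <- function() {
  tab <- builtin_code_table()
  setNames(tab$ccsr_category, tab$code)
}

toy_assoc <- function() {
  tab <- builtin_code_table()
  setNames(tab$association, tab$code)
}

# ---- independent brute-force re-evaluation of the selection criteria -----
# Written directly from the criteria text, per patient, with explicit loops;
# deliberately shares no code with the rule engine.
brute_force_potential <- function(ehr, ccsr_map, cfg) {
  suicidal <- c("MBD012", "MBD027")
  bipolar <- "MBD003"
  substance <- c("MBD017", "MBD018", "MBD019", "MBD020", "MBD021", "MBD022",
                 "MBD023", "MBD025")
  singles <- c("MBD002", "MBD003", "MBD004", "MBD005", "MBD007", "MBD008",
               "MBD009")
  table2 <- c(singles, suicidal, substance)

  included <- character()
  for (pid in ehr$patients$patient_id) {
    birth <- ehr$patients$birth_date[ehr$patients$patient_id == pid]
    encs <- ehr$encounters[ehr$encounters$patient_id == pid, ]
    dxs <- ehr$diagnoses[ehr$diagnoses$patient_id == pid, ]

    # criterion i: >=5 distinct discharge dates (or >=2 emergency) among
    # in-period encounters that carry at least one diagnosis code
    dates_all <- c(); dates_em <- c()
    for (j in seq_len(nrow(encs))) {
      e <- encs[j, ]
      if (e$discharge_date < cfg$study_start || e$discharge_date > cfg$study_end) next
      if (!any(dxs$encounter_id == e$encounter_id)) next
      dates_all <- union(dates_all, as.character(e$discharge_date))
      if (e$encounter_type == "emergency") {
        dates_em <- union(dates_em, as.character(e$discharge_date))
      }
    }
    crit_i <- length(dates_all) >= cfg$min_encounter_dates ||
      length(dates_em) >= cfg$min_emergency_dates

    # criteria ii-iv: qualifying categories at age 18-65 in period
    cats <- c()
    for (j in seq_len(nrow(dxs))) {
      d <- dxs[j, ]
      if (d$code_system != "ICD10CM") next
      if (d$discharge_date < cfg$study_start || d$discharge_date > cfg$study_end) next
      # completed-years age on the discharge date
      age <- length(seq(birth, d$discharge_date, by = "year")) - 1L
      if (age < cfg$age_low || age > cfg$age_high) next
      cat <- unname(ccsr_map[d$code])
      if (is.na(cat) || !(cat %in% table2)) next
      cats <- union(cats, cat)
    }
    has_sui <- any(cats %in% suicidal)
    has_bip <- bipolar %in% cats
    groups <- unique(c(
      intersect(cats, singles),
      if (any(cats %in% substance)) "SUB",
      if (has_sui) "SUI"
    ))
    crit_ii <- length(cats) >= 1
    crit_iii_iv <- has_sui || has_bip ||
      length(groups) >= cfg$min_other_categories

    # exclusions
    excl <- FALSE
    for (j in seq_len(nrow(dxs))) {
      d <- dxs[j, ]
      if ((d$code_system == "ICD10CM" && d$code == "F603") ||
          (d$code_system == "ICD9CM" && d$code == "30183")) excl <- TRUE
      if (d$code_system == "ICD10CM" &&
          d$discharge_date >= cfg$study_start &&
          d$discharge_date <= cfg$study_end) {
        pre <- substr(d$code, 1, 3)
        if (pre %in% sprintf("F0%d", 1:9) || pre %in% sprintf("F7%d", 0:9)) {
          excl <- TRUE
        }
      }
    }
    if (crit_i && crit_ii && crit_iii_iv && !excl) included <- c(included, pid)
  }
  sort(included)
}

# brute-force pairwise AUROC (ties count one half)
brute_force_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# planted sparse logistic benchmark used by the model tests
planted_logistic <- function(n, beta, intercept = -1, prob = 0.3) {
  p <- length(beta)
  x <- matrix(rbinom(n * p, 1, prob), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- intercept + drop(x %*% beta)
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y)
}
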