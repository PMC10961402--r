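#' Study dataset event records
#'
#' A `study_dataset` is a tibble of dose and observation event records in the
#' rectangular layout used throughout pharmacometrics: one row per dose
#' (`EVID = 1`) or observation (`EVID = 0`), with subject-constant covariates
#' repeated on every row. Times are decimal hours relative to the first dose
#' of day 1, so baseline days carry negative times.
#'
#' Columns:
#' \describe{
#'   \item{ID}{integer subject identifier, unique per subject}
#'   \item{ARM}{treatment arm, one of `"cetagliptin50"`, `"cetagliptin100"`,
#'     `"sitagliptin100"`, `"placebo"`}
#'   \item{TIME}{hours since first dose (negative during baseline days)}
#'   \item{EVID}{1 for dose rows, 0 for observation rows}
#'   \item{AMT}{dose amount in mg (`NA` on observation rows)}
#'   \item{DV}{observed value (`NA` on dose rows)}
#'   \item{DVID}{observation kind; see [observation_kinds()]}
#'   \item{MDV}{1 when `DV` is missing, else 0}
#'   \item{BLQ}{1 when the observation is below the lower limit of
#'     quantification (the `DV` then holds the LLOQ placeholder)}
#'   \item{OCC}{occasion label, e.g. `"day1"`, `"day7"`, `"day14"`, `"day-1"`,
#'     `"day15"`}
#'   \item{TBIL}{total bilirubin, umol/L (subject-constant)}
#' }
#' Additional subject-constant covariate columns (`WT`, `SEX`, `AGE`, ...) are
#' carried through unchanged.
#'
#' @param events A data frame with the columns above.
#' @param metadata Named list of dataset-level metadata. Defaults supply the
#'   dosing interval `tau = 24` h and per-analyte LLOQs.
#'
#' @return A tibble with class `study_dataset` and a `metadata` attribute.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   ID = 1L, ARM = "cetagliptin50", TIME = 0, EVID = 1L, AMT = 50,
#'   DV = NA_real_, DVID = NA_character_, MDV = 1L, BLQ = 0L,
#'   OCC = "day1", TBIL = 12
#' )
#' ds <- study_dataset(ev)
#' validate_dataset(ds)
study_dataset <- function(events, metadata = list()) {
  events <- tibble::as_tibble(events)
  needed <- c("ID", "ARM", "TIME", "EVID", "AMT", "DV", "DVID", "MDV", "BLQ",
              "OCC", "TBIL")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("study_dataset is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cetapkpd_format_error")
  }
  events$ID <- as.integer(events$ID)
  events$EVID <- as.integer(events$EVID)
  events$MDV <- as.integer(events$MDV)
  events$BLQ <- as.integer(events$BLQ)
  # canonical column order: mandatory first, extra covariates after
  extra <- setdiff(names(events), needed)
  events <- events[, c(needed, extra)]
  meta <- modifyList(default_metadata(), metadata)
  structure(events,
            metadata = meta,
            class = c("study_dataset", class(tibble::tibble())))
}

default_metadata <- function() {
  list(
    tau = 24,
    lloq = list(drug_concentration = 0.5, glp1_active = 0.017),
    units = list(
      drug_concentration = "ng/mL", dpp4_activity = "uM/min",
      glp1_active = "pM", glucose = "mmol/L", insulin = "mmol/L",
      c_peptide = "mmol/L", glucagon = "mmol/L", fpg = "mmol/L",
      ppg_2h = "mmol/L", hba1c = "%", ga = "%", TBIL = "umol/L"
    )
  )
}

#' Recognised observation kinds
#'
#' @return Character vector of the `DVID` values a [study_dataset()] may use.
#' @export
observation_kinds <- function() {
  c("drug_concentration", "dpp4_activity", "glp1_active", "glucose",
    "insulin", "c_peptide", "glucagon", "fpg", "ppg_2h", "hba1c", "ga")
}

#' Treatment arms of the trial design
#' @return Character vector of valid `ARM` values.
#' @export
study_arms <- function() {
  c("cetagliptin50", "cetagliptin100", "sitagliptin100", "placebo")
}

#' Dataset-level metadata
#' @param ds A [study_dataset()].
#' @return The metadata list (dosing interval `tau`, LLOQs, units).
#' @export
dataset_metadata <- function(ds) attr(ds, "metadata")

#' Read an event-record dataset from delimited text
#'
#' Reads a comma- or tab-delimited event table (delimiter auto-detected from
#' the header line) into a [study_dataset()]. Column names can be remapped via
#' `mapping` when the file uses a different dialect.
#'
#' @param path Path to the delimited text file.
#' @param mapping Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(ID = "SUBJ")`.
#' @param validate If `TRUE` (default) structural violations raise an error.
#'
#' @return A [study_dataset()].
#' @export
read_dataset <- function(path, mapping = NULL, validate = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("dataset file not found: ", path),
          class = "cetapkpd_format_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, locale = readr::locale(decimal_mark = "."))
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(raw)) {
        abort(paste0("mapped column not present in file: ", src),
              class = "cetapkpd_format_error")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  needed <- c("ID", "TIME", "EVID", "AMT", "DV", "DVID")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cetapkpd_format_error")
  }
  if (!"MDV" %in% names(raw)) raw$MDV <- ifelse(is.na(raw$DV), 1L, 0L)
  if (!"BLQ" %in% names(raw)) raw$BLQ <- 0L
  if (!"OCC" %in% names(raw)) raw$OCC <- NA_character_
  if (!"ARM" %in% names(raw)) raw$ARM <- NA_character_
  if (!"TBIL" %in% names(raw)) raw$TBIL <- NA_real_
  raw$DVID <- as.character(raw$DVID)
  raw$OCC <- as.character(raw$OCC)
  ds <- study_dataset(raw)
  if (validate) {
    rep <- validate_dataset(ds)
    if (nrow(rep) > 0) {
      abort(paste0("dataset failed validation:\n",
                   paste(utils::capture.output(print(rep)), collapse = "\n")),
            class = "cetapkpd_validation_error")
    }
  }
  ds
}

#' Write an event-record dataset to delimited text
#'
#' Writes with a fixed column order and full-precision number formatting so
#' that two writes of the same dataset are byte-identical and
#' `read_dataset(write_dataset(ds))` round-trips.
#'
#' @param ds A [study_dataset()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, delim = ",") {
  stopifnot(inherits(ds, "study_dataset"))
  readr::write_delim(tibble::as_tibble(ds), path, delim = delim, na = "")
  invisible(path)
}

#' Validate a study dataset
#'
#' Checks the structural invariants of the event-record model. Violations are
#' returned as data, not raised: an empty report means the dataset is valid.
#'
#' @param ds A [study_dataset()].
#' @return A tibble with columns `ID` (subject, `NA` for dataset-level rules),
#'   `rule` and `detail`, one row per violation.
#' @export
validate_dataset <- function(ds) {
  viol <- list()
  add <- function(id, rule, detail) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      ID = as.integer(id), rule = rule, detail = detail)
  }
  meta <- dataset_metadata(ds)
  if (!is.numeric(meta$tau) || meta$tau <= 0) {
    add(NA, "tau_positive", "dosing interval tau must be > 0")
  }
  bad_arm <- unique(ds$ARM[!ds$ARM %in% study_arms() & !is.na(ds$ARM)])
  for (a in bad_arm) add(NA, "unknown_arm", paste0("unknown arm: ", a))
  obs <- ds[ds$EVID == 0L, ]
  bad_kind <- unique(obs$DVID[!obs$DVID %in% observation_kinds()])
  for (k in bad_kind) {
    add(NA, "unknown_observation_kind", paste0("unknown DVID: ", k))
  }
  # per-subject rules
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    if (is.unsorted(sub$TIME)) {
      add(id, "non_monotone_time",
          paste0("times not sorted for subject ", id))
    }
    if (length(unique(sub$ARM[!is.na(sub$ARM)])) > 1) {
      add(id, "arm_constant", "subject assigned to more than one arm")
    }
    doses <- sub[sub$EVID == 1L, ]
    if (any(!is.na(doses$DV))) {
      add(id, "dose_with_dv", "dose row carries a non-missing DV")
    }
    if (any(is.na(doses$AMT) | doses$AMT <= 0)) {
      add(id, "dose_amount_positive", "dose row with AMT missing or <= 0")
    }
    if (any(doses$TIME < 0, na.rm = TRUE)) {
      add(id, "dose_time_nonnegative", "dose row before time 0")
    }
    o <- sub[sub$EVID == 0L, ]
    if (any(o$TIME < -72, na.rm = TRUE)) {
      add(id, "observation_time_range", "observation earlier than -72 h")
    }
    neg_ok <- o$DVID %in% c("fpg", "ppg_2h", "hba1c", "ga")  # change scores allowed elsewhere
    if (any(!is.na(o$DV) & o$DV < 0 & !o$DVID %in% "glp1_active" & !neg_ok &
            o$DVID != "dpp4_activity" & o$DVID %in% c("drug_concentration",
            "glucose", "insulin", "c_peptide", "glucagon"))) {
      add(id, "value_nonnegative", "negative value for a concentration-like analyte")
    }
    arm <- sub$ARM[1]
    if (identical(arm, "placebo")) {
      lloq <- meta$lloq$drug_concentration %||% 0
      conc <- o[o$DVID == "drug_concentration" & !is.na(o$DV), ]
      if (any(conc$DV > lloq & conc$BLQ == 0L)) {
        add(id, "placebo_concentration",
            "placebo subject has drug concentrations above LLOQ")
      }
    }
  }
  # two subjects sharing an ID are detectable in long format as one ID whose
  # subject-constant fields (arm, covariates) disagree between rows
  covar_cols <- intersect(c("ARM", "TBIL", "WT", "SEX", "AGE"), names(ds))
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, covar_cols, drop = FALSE]
    n_distinct <- nrow(unique(sub))
    if (n_distinct > 1) {
      add(id, "duplicate_subject_id",
          paste0("ID ", id, " has conflicting subject-level fields; ",
                 "two subjects may share an id"))
    }
  }
  if (length(viol) == 0) {
    tibble::tibble(ID = integer(), rule = character(), detail = character())
  } else {
    dplyr::bind_rows(viol)
  }
}

#' Split a dataset into per-subject records
#'
#' @param ds A [study_dataset()].
#' @param dvid Observation kind to keep (default `"drug_concentration"`).
#' @param drop_blq Drop BLQ observations (default `FALSE`).
#' @return A list, one element per subject, each with `id`, `arm`,
#'   `dose_t`, `dose_amt`, `obs` (tibble TIME/DV/OCC/BLQ) and `covariates`.
#' @export
subject_records <- function(ds, dvid = "drug_concentration", drop_blq = FALSE) {
  covar_cols <- intersect(c("TBIL", "WT", "SEX", "AGE"), names(ds))
  lapply(split(tibble::as_tibble(ds), ds$ID), function(sub) {
    doses <- sub[sub$EVID == 1L, ]
    obs <- sub[sub$EVID == 0L & sub$DVID %in% dvid, ]
    if (drop_blq) obs <- obs[obs$BLQ == 0L, ]
    list(
      id = sub$ID[1],
      arm = sub$ARM[1],
      dose_t = doses$TIME,
      dose_amt = doses$AMT,
      obs = obs[, c("TIME", "DV", "DVID", "OCC", "BLQ")],
      covariates = as.list(sub[1, covar_cols, drop = FALSE])
    )
  })
}
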