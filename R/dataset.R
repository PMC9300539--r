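# NONMEM-style longitudinal record tables. One flexible CSV dialect:
# comma-separated with a header row. Mandatory columns:
#   ID    subject identifier
#   TIME  hours since the subject's first administration (>= 0)
#   EVID  1 = dose, 0 = observation
#   CMT   compartment/series code: "pac", "rtv", "tsp1"
#   AMT   dose amount in mg (doses only)
#   DV    observed value (pac/rtv ng/mL, tsp1 ng/mL per 1e6 platelets)
#   MDV   1 = missing observation
#   OCC   occasion (sequential paclitaxel dose administrations)
#   FORM  formulation code for oral doses ("solution","capsule","tablet")
#   DDI   daily-dose index for oral paclitaxel doses (1 or 2)
# Unknown extra columns are preserved opaquely.

DATASET_COLUMNS <- c("ID", "TIME", "EVID", "CMT", "AMT", "DV", "MDV",
                     "OCC", "FORM", "DDI")

#' Validate a study dataset
#'
#' Checks the record-table contract: mandatory columns present, times
#' non-negative and sorted within subject, dose rows carrying positive
#' amounts and a known compartment code, observation rows carrying a
#' value or a set missing flag. All violations are collected and
#' reported together with the offending row numbers.
#'
#' @param dataset A data frame in the study-dataset layout.
#' @return The dataset, invisibly, if valid; otherwise an error of
#'   class `pax_validation_error` listing every offending row.
#' @export
validate_dataset <- function(dataset) {
  problems <- character(0)
  miss <- setdiff(DATASET_COLUMNS, names(dataset))
  if (length(miss)) {
    stop(errorCondition(
      paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")),
      class = c("pax_validation_error", "error")))
  }
  bad <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(rows, collapse = ", "), ")"))
  }
  bad(which(!dataset$EVID %in% c(0L, 1L)), "EVID must be 0 or 1")
  bad(which(dataset$TIME < 0), "negative TIME")
  for (id in unique(dataset$ID)) {
    rows <- which(dataset$ID == id)
    if (is.unsorted(dataset$TIME[rows]))
      bad(rows[1], paste0("times not sorted for subject ", id))
  }
  dose <- dataset$EVID == 1L
  bad(which(dose & (is.na(dataset$AMT) | dataset$AMT <= 0)),
      "dose row without positive AMT")
  bad(which(dose & !dataset$CMT %in% c("pac", "rtv")),
      "dose row with unknown CMT")
  obs <- dataset$EVID == 0L
  bad(which(obs & !dataset$CMT %in% c("pac", "rtv", "tsp1")),
      "observation row with unknown CMT")
  bad(which(obs & is.na(dataset$DV) & dataset$MDV != 1L),
      "observation without DV and without missing flag")
  pacd <- which(dose & dataset$CMT == "pac")
  bad(pacd[!dataset$FORM[pacd] %in% c("solution", "capsule", "tablet")],
      "oral paclitaxel dose with unknown formulation code")
  bad(pacd[!dataset$DDI[pacd] %in% c(1L, 2L)],
      "oral paclitaxel dose with invalid daily-dose index")
  if (length(problems))
    stop(errorCondition(
      paste0("invalid study dataset:\n  ",
             paste(problems, collapse = "\n  ")),
      class = c("pax_validation_error", "error")))
  invisible(dataset)
}

#' Read a study dataset from CSV
#'
#' Reads the comma-separated record table, coerces the mandatory
#' columns to their expected types and validates the result
#' ([validate_dataset()]). Unknown columns are kept unchanged.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated data frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop("dataset file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(DATASET_COLUMNS, names(d))
  if (length(miss))
    stop(errorCondition(
      paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")),
      class = c("pax_validation_error", "error")))
  for (col in c("TIME", "AMT", "DV"))
    d[[col]] <- as.numeric(d[[col]])
  for (col in c("EVID", "MDV", "OCC", "DDI"))
    d[[col]] <- as.integer(d[[col]])
  d$CMT <- as.character(d$CMT)
  d$FORM <- as.character(d$FORM)
  validate_dataset(d)
  d
}

#' Write a study dataset to CSV
#'
#' Numeric columns are serialised with 17 significant digits so a
#' write/read cycle round-trips the values exactly.
#'
#' @param dataset The record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  out <- dataset
  for (col in names(out))
    if (is.double(out[[col]])) {
      x <- sprintf("%.17g", out[[col]])
      x[is.na(out[[col]])] <- NA
      out[[col]] <- x
    }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Assign occasion numbers to a study dataset
#'
#' Each paclitaxel dose administration is one occasion: dose rows are
#' numbered 1..n per subject in time order and every other row inherits
#' the occasion of the most recent paclitaxel dose (rows before the
#' first dose get occasion 1). Numbering is independent across
#' subjects.
#'
#' @param dataset The record table (dose rows must be present).
#' @return The dataset with the `OCC` column rewritten.
#' @export
assign_occasions <- function(dataset) {
  stopifnot(all(c("ID", "TIME", "EVID", "CMT") %in% names(dataset)))
  dataset$OCC <- 1L
  for (id in unique(dataset$ID)) {
    rows <- which(dataset$ID == id)
    d <- dataset[rows, ]
    pd <- which(d$EVID == 1L & d$CMT == "pac")
    if (!length(pd)) next
    ord <- pd[order(d$TIME[pd])]
    occ_of_dose <- integer(nrow(d))
    occ_of_dose[ord] <- seq_along(ord)
    dose_times <- d$TIME[ord]
    occ <- findInterval(d$TIME, dose_times)
    occ[occ == 0L] <- 1L
    occ[ord] <- seq_along(ord)  # doses own their occasion
    dataset$OCC[rows] <- occ
  }
  dataset
}
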