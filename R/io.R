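#' Read and write NONMEM-style event-record datasets
#'
#' The on-disk format is a CSV with one row per event: dose rows
#' (`EVID = 1`) carry `AMT` (mg), `CMT` (1 oral/central, 2 IM depot),
#' `DUR` (h of zero-order input) and `OCC` (IM injection occasion);
#' observation rows (`EVID = 0`) carry `DV` (ng/mL), `MDV`, `BLQ`
#' (censored below the LLOQ) and the route governing the residual error.
#' Covariates (`SEX`, `AGE`, `WT`, `BMI`) and the assay `LLOQ` repeat on
#' every row of a subject. Times are hours since the subject's first
#' dose.
#'
#' `read_pk_dataset` validates structure on the way in: required
#' columns, non-negative and non-decreasing times within subject, dose
#' rows with positive amounts and no observation value, observation rows
#' preceded by at least one dose.
#'
#' @param path file path.
#' @return `read_pk_dataset`: the validated event-record data frame.
#' @export
read_pk_dataset <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ID", "TIME", "AMT", "DV", "EVID", "CMT", "MDV", "ROUTE",
                "DUR", "OCC", "BLQ", "SEX", "AGE", "WT", "BMI", "LLOQ")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_pk_dataset(tab)
  message("read ", length(unique(tab$ID)), " subjects, ",
          sum(tab$EVID == 0), " observations (",
          sum(tab$EVID == 0 & tab$BLQ == 1), " BLQ), ",
          sum(tab$EVID == 1), " dose records")
  tab
}

validate_pk_dataset <- function(tab) {
  if (any(tab$TIME < 0)) stop("negative times in dataset", call. = FALSE)
  doses <- tab$EVID == 1
  if (any(is.na(tab$AMT[doses])) || any(tab$AMT[doses] <= 0)) {
    stop("dose records must have positive AMT", call. = FALSE)
  }
  if (any(!is.na(tab$DV[doses]))) {
    stop("dose records must not carry observations", call. = FALSE)
  }
  if (any(is.na(tab$DV[!doses & tab$MDV == 0]))) {
    stop("non-missing observation records must carry DV", call. = FALSE)
  }
  if (any(!tab$ROUTE[doses] %in% c("oral", "im"))) {
    stop("unknown route code in dose records", call. = FALSE)
  }
  for (id in unique(tab$ID)) {
    st <- tab[tab$ID == id, , drop = FALSE]
    if (is.unsorted(st$TIME)) {
      stop("times are not non-decreasing within subject ", id, call. = FALSE)
    }
    obs_t <- st$TIME[st$EVID == 0]
    if (length(obs_t)) {
      first_dose <- suppressWarnings(min(st$TIME[st$EVID == 1]))
      if (!is.finite(first_dose) || min(obs_t) <= first_dose) {
        stop("subject ", id, " has an observation before any dose",
             call. = FALSE)
      }
    }
  }
  invisible(tab)
}

#' @rdname read_pk_dataset
#' @param data event-record data frame to write.
#' @return `write_pk_dataset`: the path, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  validate_pk_dataset(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
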