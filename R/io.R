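#' Event-table dataset conventions
#'
#' Longitudinal datasets use a NONMEM-style event format, one row per dosing
#' or observation event:
#'
#' * `ID` subject identifier; `TIME` in hours (observations from the run-in
#'   period may carry negative times; doses never do).
#' * Dose rows: `EVID = 1`, `AMT` > 0 (total inhaled ug), `CMT` 1
#'   (budesonide) or 2 (formoterol), no `DV`, `MDV = 1`. Optional `ADDL`
#'   and `II` encode `ADDL` additional doses every `II` hours.
#' * Observation rows: `EVID = 0`, `DV` observed value, `MDV` 0 (usable) or
#'   1 (missing/censored), `DVID` one of `conc_BUD`, `conc_FMT`, `ECP`,
#'   `FEV1`, `ACT`, and `BLQ` 1 for concentrations below the LLOQ.
#' * Covariate columns `SEX`, `AGE`, `WT`, `HT`, `DUR`, `GENO` are constant
#'   within subject.
#'
#' @name event_table
#' @keywords internal
NULL

ET_COLUMNS <- c("ID", "TIME", "AMT", "EVID", "CMT", "DV", "MDV", "DVID",
                "BLQ", "ADDL", "II", "SEX", "AGE", "WT", "HT", "DUR", "GENO")

#' Validate an event table
#'
#' Enforces the schema of the package's NONMEM-style dataset: required
#' columns, dose/observation consistency (dose rows have `AMT > 0` and no
#' `DV`; observation rows have a `DV` or `MDV = 1`), non-negative dose
#' times, and non-decreasing time within subject. Violations raise an error
#' naming the first offending row and column.
#'
#' @param data Data frame.
#' @return `data`, invisibly, on success.
#' @export
validate_dataset <- function(data) {
  required <- c("ID", "TIME", "AMT", "EVID", "DV", "MDV", "DVID")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- function(rows, col, msg) {
    if (any(rows)) {
      stop("row ", which(rows)[1], ", column ", col, ": ", msg)
    }
  }
  dose <- data$EVID == 1
  bad(dose & (is.na(data$AMT) | data$AMT <= 0), "AMT",
      "dose rows require AMT > 0")
  bad(dose & !is.na(data$DV), "DV", "dose rows must not carry a DV")
  bad(dose & data$TIME < 0, "TIME", "dose times must be non-negative")
  obs <- data$EVID == 0
  bad(obs & is.na(data$DV) & data$MDV != 1, "DV",
      "observation rows need a DV or MDV = 1")
  bad(obs & !is.na(data$AMT) & data$AMT != 0, "AMT",
      "observation rows must not carry an AMT")
  for (id in unique(data$ID)) {
    tt <- data$TIME[data$ID == id]
    if (is.unsorted(tt)) {
      stop("row ", which(data$ID == id)[which(diff(tt) < 0)[1] + 1],
           ", column TIME: time must be non-decreasing within subject ", id)
    }
  }
  invisible(data)
}

#' Expand ADDL/II dose shorthand into explicit dose rows
#'
#' @param data Validated event table, possibly with `ADDL`/`II` columns.
#' @return Event table with one row per dose and `ADDL`/`II` zeroed,
#'   re-sorted by subject and time.
#' @export
expand_doses <- function(data) {
  if (!all(c("ADDL", "II") %in% names(data))) return(data)
  addl <- ifelse(is.na(data$ADDL), 0, data$ADDL)
  todo <- which(data$EVID == 1 & addl > 0)
  if (length(todo) == 0) return(data)
  extra <- lapply(todo, function(i) {
    k <- seq_len(addl[i])
    rows <- data[rep(i, length(k)), , drop = FALSE]
    rows$TIME <- data$TIME[i] + k * data$II[i]
    rows
  })
  out <- rbind(data, do.call(rbind, extra))
  out$ADDL <- 0
  out$II <- 0
  out <- out[order(out$ID, out$TIME, -out$EVID), ]
  rownames(out) <- NULL
  out
}

#' Read an event-table dataset
#'
#' Reads a CSV in the package's NONMEM-style dialect and validates it
#' against the schema (see [validate_dataset()]).
#'
#' @param path CSV path.
#' @param expand Expand `ADDL`/`II` dose shorthand into explicit rows?
#'   Default `FALSE` (keeps read/write round trips byte-stable).
#' @return Validated event-table data frame.
#' @export
read_dataset <- function(path, expand = FALSE) {
  if (!file.exists(path)) stop("dataset not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(data)
  if (expand) data <- expand_doses(data)
  data
}

#' Write an event-table dataset
#'
#' Writes CSV with canonical formatting (fixed column order where the
#' standard columns are present, numbers at up to 10 significant digits,
#' empty fields for NA), so a read/write cycle of a canonical file is
#' byte-stable.
#'
#' @param data Event-table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  ord <- c(intersect(ET_COLUMNS, names(data)), setdiff(names(data), ET_COLUMNS))
  data <- data[, ord, drop = FALSE]
  num <- vapply(data, is.numeric, logical(1))
  for (j in which(num)) {
    data[[j]] <- ifelse(is.na(data[[j]]), "",
                        format(data[[j]], digits = 10, trim = TRUE,
                               scientific = FALSE))
  }
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split an event table into prepared per-subject structures
#'
#' Builds the per-subject structure consumed by [nlme_model()] predictions:
#' observation times and values for one endpoint (BLQ and `MDV = 1` rows
#' dropped -- the M1 method), the subject's dose history for the relevant
#' compartment, and covariates.
#'
#' @param data Event table.
#' @param dvid Endpoint to extract; default: the single endpoint present.
#' @param cmt Dose compartment to extract (1 budesonide, 2 formoterol);
#'   default: all dose rows.
#' @param keep_blq Also collect the times of BLQ observations (field
#'   `times_cens`), for censoring-aware (M3) likelihoods. Default `FALSE`
#'   (M1: censored rows are simply dropped).
#' @return List of subjects, each
#'   `list(id, times, dv, doses = data.frame(time, amt), cov, times_cens)`.
#'   Subjects without usable observations are omitted.
#' @export
prepare_subjects <- function(data, dvid = NULL, cmt = NULL, keep_blq = FALSE) {
  validate_dataset(data)
  data <- expand_doses(data)
  if (is.null(dvid)) {
    eps <- unique(data$DVID[data$EVID == 0])
    if (length(eps) != 1) {
      stop("dataset has endpoints ", paste(eps, collapse = ", "),
           "; specify dvid")
    }
    dvid <- eps
  }
  blq <- if ("BLQ" %in% names(data)) !is.na(data$BLQ) & data$BLQ == 1 else FALSE
  keep_obs <- data$EVID == 0 & data$DVID == dvid & data$MDV == 0 & !blq
  keep_dose <- data$EVID == 1 & (if (is.null(cmt)) TRUE else data$CMT == cmt)
  cov_cols <- intersect(c("SEX", "AGE", "WT", "HT", "DUR", "GENO"), names(data))
  cens <- data$EVID == 0 & data$DVID == dvid & blq
  lapply(split(seq_len(nrow(data)), data$ID), function(ix) {
    oi <- ix[keep_obs[ix]]
    # under M3 a subject with only censored observations still informs the
    # likelihood; under M1 such a subject carries no usable data
    if (length(oi) == 0 && (!keep_blq || !any(cens[ix]))) return(NULL)
    di <- ix[keep_dose[ix]]
    cov <- as.list(data[ix[1], cov_cols, drop = FALSE])
    names(cov) <- c(SEX = "sex", AGE = "age", WT = "weight", HT = "height",
                    DUR = "duration", GENO = "genotype")[cov_cols]
    list(id = data$ID[ix[1]], times = data$TIME[oi], dv = data$DV[oi],
         doses = data.frame(time = data$TIME[di], amt = data$AMT[di]),
         cov = cov,
         times_cens = if (keep_blq) data$TIME[ix[cens[ix]]] else numeric(0))
  }) |> Filter(f = Negate(is.null))
}
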