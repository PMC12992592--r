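#' Read an LNP formulation table
#'
#' Reads a CSV of lipid-nanoparticle formulation records: one row per LNP,
#' with component SMILES, molar ratios (mol%), experimental context, and a
#' raw delivery readout. Optional composition fields are tri-state: a value,
#' the literal string \code{"none"} (component reported absent), or an empty
#' cell (unreported, stored as \code{NA}).
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param required character vector of columns that must be present.
#' @return A data frame of class \code{lnp_formulations}, one row per input
#'   row, with a \code{row} column preserving source row numbers for error
#'   reporting.
#' @export
read_formulation_table <- function(path,
                                   required = c("lnp_id",
                                                "ionizable_lipid_smiles",
                                                "ratio_ionizable",
                                                "publication_id",
                                                "delivery_context",
                                                "readout_value")) {
  if (!file.exists(path)) stop("formulation table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("formulation table schema error: missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  ratio_cols <- grep("^ratio_", names(tab), value = TRUE)
  for (cc in c(ratio_cols, "readout_value", "il_to_na_mass_ratio")) {
    if (!cc %in% names(tab)) next
    raw <- tab[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0L) {
      stop("unparseable value in column '", cc, "' at row ", bad[1L],
           ": '", raw[bad[1L]], "'")
    }
    tab[[cc]] <- num
  }
  tab$row <- seq_len(nrow(tab))
  class(tab) <- c("lnp_formulations", class(tab))
  tab
}

#' Validate a formulation record
#'
#' Checks one record against the formulation invariants: molar ratios are
#' non-negative and sum to 100 within \code{tolerance}; the lipid-to-nucleic
#' acid mass ratio, when present, is positive. Violations are returned as
#' data, not raised as errors, so whole tables can be screened.
#'
#' @param record a single-row data frame (or list) with \code{ratio_*}
#'   columns and optionally \code{il_to_na_mass_ratio}.
#' @param tolerance allowed deviation of the ratio sum from 100 (mol%).
#' @return character vector of violations; empty when the record is valid.
#' @export
validate_formulation <- function(record, tolerance = 0.5) {
  record <- as.list(record)
  out <- character(0)
  ratio_fields <- grep("^ratio_", names(record), value = TRUE)
  ratios <- unlist(record[ratio_fields])
  ratios <- ratios[!is.na(ratios)]
  if (any(ratios < 0)) {
    out <- c(out, paste0("molar_ratios: negative ratio in ",
                         paste(ratio_fields[!is.na(unlist(record[ratio_fields])) &
                                              unlist(record[ratio_fields]) < 0],
                               collapse = ", ")))
  }
  if (length(ratios) > 0L) {
    s <- sum(ratios)
    if (abs(s - 100) > tolerance) {
      out <- c(out, sprintf(
        "molar_ratios: sum %.4g differs from 100 by more than tolerance %.4g",
        s, tolerance))
    }
  }
  mr <- record[["il_to_na_mass_ratio"]]
  if (!is.null(mr) && !is.na(mr) && mr <= 0) {
    out <- c(out, "il_to_na_mass_ratio: must be > 0 when present")
  }
  out
}

#' Standardize delivery readouts within publication/context groups
#'
#' Delivery readouts from different screens are not directly comparable:
#' scales, assays and units differ across publications and between in vitro
#' and in vivo arms of the same study. Each
#' \code{(publication_id, delivery_context)} group is therefore z-scored to
#' mean 0 and sample standard deviation 1. When the positive raw values of a
#' group span at least \code{log_trigger_ratio} (max/min), they are log10
#' transformed before z-scoring, so that readouts spanning orders of
#' magnitude do not reduce to a few outliers.
#'
#' @param records an \code{lnp_formulations} data frame (or any data frame
#'   with \code{publication_id}, \code{delivery_context},
#'   \code{readout_value}).
#' @param log_trigger_ratio ratio of max to min positive raw values at or
#'   above which log10 is applied first. Default 100 (two orders of
#'   magnitude).
#' @return list with \code{records} (input plus \code{standardized_readout})
#'   and \code{groups}, a per-group audit data frame (group key, n,
#'   \code{log_applied}, raw mean and sd of the possibly log-transformed
#'   values).
#' @export
standardize_delivery <- function(records, log_trigger_ratio = 100) {
  need <- c("publication_id", "delivery_context", "readout_value")
  stopifnot(all(need %in% names(records)))
  key <- interaction(records$publication_id, records$delivery_context,
                     drop = TRUE, sep = "|")
  records$standardized_readout <- NA_real_
  groups <- data.frame(publication_id = character(0),
                       delivery_context = character(0),
                       n = integer(0), log_applied = logical(0),
                       mean = numeric(0), sd = numeric(0),
                       stringsAsFactors = FALSE)
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- records$readout_value[idx]
    if (any(is.na(v))) stop("missing readout_value in group ", g)
    log_applied <- FALSE
    if (all(v > 0) && max(v) / min(v) >= log_trigger_ratio) {
      v <- log10(v)
      log_applied <- TRUE
    }
    m <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("degenerate standardization group (sd = 0): ", g)
    }
    records$standardized_readout[idx] <- (v - m) / s
    groups <- rbind(groups, data.frame(
      publication_id = records$publication_id[idx[1L]],
      delivery_context = records$delivery_context[idx[1L]],
      n = length(idx), log_applied = log_applied,
      mean = m, sd = s, stringsAsFactors = FALSE))
  }
  list(records = records, groups = groups)
}
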