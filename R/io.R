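.required_cols <- c("patient_id", "label", "rCBV_max", "TBR_max", "TBR_mean",
                    "Slope_suv_per_h", "TTP_min")
.param_cols <- c("rCBV_max", "TBR_max", "TBR_mean", "Slope_suv_per_h",
                 "TTP_min")

#' Read a patient parameter table
#'
#' Comma-separated, UTF-8, "." decimal.  Required columns:
#' `patient_id`, `label`, `rCBV_max`, `TBR_max`, `TBR_mean`,
#' `Slope_suv_per_h`, `TTP_min`; unknown columns are preserved.  Labels
#' are normalized (trimmed, case-folded) to TP/TRC; duplicate patient ids,
#' missing columns and non-numeric parameter cells are rejected with the
#' offending column or row named.
#'
#' @param path CSV file path.
#' @return patient table (`data.frame`).
#' @export
read_patient_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  miss <- .required_cols[!.required_cols %in% names(raw)]
  if (length(miss))
    stop("patient table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) stop("patient table is empty")
  for (p in .param_cols) {
    v <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(is.na(v) & !(is.na(raw[[p]]) | trimws(raw[[p]]) == "NA"))
    if (length(bad))
      stop("non-numeric value in column ", p, " at row ", bad[1],
           ": '", raw[[p]][bad[1]], "'")
    raw[[p]] <- v
  }
  raw$label <- .check_labels(raw$label)
  if (anyDuplicated(raw$patient_id))
    stop("duplicate patient_id values")
  raw
}

#' Write a patient parameter table
#'
#' @param table patient table.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a TAC to CSV / read it back
#'
#' Columns: `frame_time_min`, `tumor_mean_bq_g`, `tumor_max_bq_g`,
#' `background_mean_bq_g`; weight and dose travel in a JSON sidecar-style
#' header comment-free pair of extra columns (constant per file).
#'
#' @param tac a [tac()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_tac <- function(tac, path) {
  stopifnot(inherits(tac, "tac"))
  df <- data.frame(frame_time_min = tac$frame_mid_times,
                   tumor_mean_bq_g = tac$tumor_mean,
                   tumor_max_bq_g = tac$tumor_max,
                   background_mean_bq_g = tac$background_mean,
                   weight_g = tac$weight_g, injected_bq = tac$injected_bq)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @param path CSV file written by [write_tac()].
#' @export
read_tac <- function(path) {
  df <- read.csv(path)
  need <- c("frame_time_min", "tumor_mean_bq_g", "tumor_max_bq_g",
            "background_mean_bq_g", "weight_g", "injected_bq")
  miss <- need[!need %in% names(df)]
  if (length(miss)) stop("TAC file lacks column(s): ", paste(miss, collapse = ", "))
  tac(df$frame_time_min, df$tumor_mean_bq_g, df$tumor_max_bq_g,
      df$background_mean_bq_g, df$weight_g[1], df$injected_bq[1])
}

.flow_to_list <- function(flow) {
  cm_list <- function(cm) {
    if (is.null(cm)) return(NULL)
    list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
         sens = cm$sens, spec = cm$spec, acc = cm$acc,
         ppv = cm$ppv, npv = cm$npv, ci95 = cm$ci95)
  }
  list(n_total = flow$n_total, n_stage1_tp = flow$n_stage1_tp,
       n_remaining = flow$n_remaining, n_stage2_tp = flow$n_stage2_tp,
       n_stage2_trc = flow$n_stage2_trc,
       cutoffs = unclass(flow$cutoffs),
       stage1 = cm_list(flow$stage1), stage2 = cm_list(flow$stage2),
       overall = cm_list(flow$overall))
}

#' Write a classification report
#'
#' Emits a machine-readable JSON file (full precision) and a
#' human-readable text file in which rates are rounded half away from
#' zero — two decimals for rates, integer percent for headline accuracy
#' (so 0.625 prints as 0.63 and 86.5\% as 87\%).
#'
#' @param flow a `flow_summary` from [evaluate_flow()].
#' @param performance optional per-parameter table from
#'   [cohort_performance()], embedded in the JSON.
#' @param path output path stem; writes `<path>.json` and `<path>.txt`.
#' @return named character vector of the two file paths, invisibly.
#' @export
report <- function(flow, performance = NULL, path) {
  stopifnot(inherits(flow, "flow_summary"))
  if (flow$n_total == 0L) stop("refusing to report on an empty cohort")
  payload <- .flow_to_list(flow)
  if (!is.null(performance)) payload$parameter_performance <- performance
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  con <- file(txt_path, "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(flow)
  invisible(c(json = json_path, text = txt_path))
}
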