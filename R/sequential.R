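#' Cutoff triple of the sequential classifier
#'
#' @param rcbv_cut rCBVmax threshold (ratio, > 0); stage 1 calls TP above.
#' @param tbr_cut TBRmax threshold (ratio, > 0); stage 2 calls TP above.
#' @param slope_cut late-slope threshold (SUV/h); stage 2 calls TP below.
#' @return a `sequential_cutoffs` object.
#' @export
sequential_cutoffs <- function(rcbv_cut, tbr_cut, slope_cut) {
  stopifnot(is.finite(rcbv_cut) || is.infinite(rcbv_cut),
            is.numeric(tbr_cut), is.numeric(slope_cut))
  if (is.finite(rcbv_cut) && rcbv_cut <= 0) stop("rcbv_cut must be positive")
  if (is.finite(tbr_cut) && tbr_cut <= 0) stop("tbr_cut must be positive")
  structure(list(rcbv_cut = rcbv_cut, tbr_cut = tbr_cut,
                 slope_cut = slope_cut),
            class = "sequential_cutoffs")
}

.need_cols <- function(cohort, cols) {
  miss <- cols[!cols %in% names(cohort)]
  if (length(miss))
    stop("missing parameter column(s): ", paste(miss, collapse = ", "))
  for (cc in cols)
    if (any(is.na(cohort[[cc]])))
      stop("missing values in ", cc, " are not allowed")
}

#' Combined static/dynamic PET rule
#'
#' Calls TP when either PET parameter crosses its cutoff — TBRmax
#' strictly above `tbr_cut` or Slope strictly below `slope_cut` — and TRC
#' otherwise.  This is the stage-2 rule of the sequential classifier,
#' usable on its own.
#'
#' @param records patient table (or single-row data.frame) with `TBR_max`
#'   and `Slope_suv_per_h`.
#' @param cutoffs a [sequential_cutoffs()].
#' @return character vector of TP/TRC calls.
#' @export
classify_combined_pet <- function(records, cutoffs) {
  stopifnot(inherits(cutoffs, "sequential_cutoffs"))
  .need_cols(records, c("TBR_max", "Slope_suv_per_h"))
  ifelse(records$TBR_max > cutoffs$tbr_cut |
           records$Slope_suv_per_h < cutoffs$slope_cut, "TP", "TRC")
}

#' Two-stage sequential PWI + PET classification
#'
#' Stage 1 calls TP whenever rCBVmax strictly exceeds `rcbv_cut` (the
#' high-specificity perfusion gate); patients below the gate go to stage
#' 2, the combined PET rule of [classify_combined_pet()].  TRC can only
#' ever be called at stage 2.
#'
#' @param records patient table with `rCBV_max`, `TBR_max`,
#'   `Slope_suv_per_h`.
#' @param cutoffs a [sequential_cutoffs()].
#' @return data.frame with columns `call` (TP/TRC), `stage` (1/2) and
#'   `triggering_parameter` (`rCBV_max`, `TBR_max`, `Slope`, both, or
#'   `NA` for TRC calls).
#' @export
classify_sequential <- function(records, cutoffs) {
  stopifnot(inherits(cutoffs, "sequential_cutoffs"))
  .need_cols(records, c("rCBV_max", "TBR_max", "Slope_suv_per_h"))
  stage1 <- records$rCBV_max > cutoffs$rcbv_cut
  pet_call <- classify_combined_pet(records, cutoffs)
  call <- ifelse(stage1, "TP", pet_call)
  tbr_hit <- records$TBR_max > cutoffs$tbr_cut
  slope_hit <- records$Slope_suv_per_h < cutoffs$slope_cut
  trigger <- ifelse(stage1, "rCBV_max",
             ifelse(tbr_hit & slope_hit, "TBR_max+Slope",
             ifelse(tbr_hit, "TBR_max",
             ifelse(slope_hit, "Slope", NA_character_))))
  data.frame(call = call, stage = ifelse(stage1, 1L, 2L),
             triggering_parameter = trigger)
}

#' Fit the three sequential cutoffs on a training cohort
#'
#' Each cutoff is derived independently on the full cohort by maximizing
#' the product of sensitivity and specificity on its ROC curve:
#' rCBVmax and TBRmax higher-positive, Slope lower-positive.
#'
#' @param cohort labeled patient table with all three parameters.
#' @return a [sequential_cutoffs()].
#' @export
fit_cutoffs <- function(cohort) {
  labels <- .check_labels(cohort$label)
  if (length(unique(labels)) < 2L)
    stop("cannot fit cutoffs on a single-class cohort")
  .need_cols(cohort, c("rCBV_max", "TBR_max", "Slope_suv_per_h"))
  cut1 <- function(col, dirn)
    optimal_cutoff(roc_auc(cohort[[col]], labels, dirn)$curve)$cutoff
  sequential_cutoffs(rcbv_cut = cut1("rCBV_max", "higher"),
                     tbr_cut = cut1("TBR_max", "higher"),
                     slope_cut = cut1("Slope_suv_per_h", "lower"))
}

#' Patient-flow accounting of the sequential classifier
#'
#' Applies the two-stage rule to a labeled cohort and tallies the flow:
#' how many patients the rCBV gate classifies at stage 1, how many remain,
#' and how the combined PET rule splits the remainder — together with
#' confusion metrics for the stage-1-only rule (everyone not gated
#' counted as a TRC call), for stage 2 on the remaining subset alone, and
#' for the full sequential rule on all patients.
#'
#' @param cohort labeled patient table.
#' @param cutoffs a [sequential_cutoffs()].
#' @return a `flow_summary`: counts `n_total`, `n_stage1_tp`,
#'   `n_remaining`, `n_stage2_tp`, `n_stage2_trc`; `stage1`, `stage2`,
#'   `overall` [confusion()] blocks; `cutoffs`; per-patient `calls`.
#' @export
evaluate_flow <- function(cohort, cutoffs) {
  labels <- .check_labels(cohort$label)
  staged <- classify_sequential(cohort, cutoffs)
  s1 <- staged$stage == 1L
  res <- structure(list(
    n_total = nrow(cohort),
    n_stage1_tp = sum(s1),
    n_remaining = sum(!s1),
    n_stage2_tp = sum(!s1 & staged$call == "TP"),
    n_stage2_trc = sum(!s1 & staged$call == "TRC"),
    stage1 = confusion(ifelse(s1, "TP", "TRC"), labels),
    stage2 = if (any(!s1)) confusion(staged$call[!s1], labels[!s1]) else NULL,
    overall = confusion(staged$call, labels),
    cutoffs = cutoffs, calls = staged),
    class = "flow_summary")
  res
}

#' Leave-one-out cross-validation of the whole procedure
#'
#' For each patient, refits all three cutoffs on the remaining `n - 1`
#' patients and classifies the held-out patient with the sequential rule;
#' the held-out calls aggregate into overall accuracy, sensitivity and
#' specificity.  Folds whose training set lacks a class are skipped with
#' a warning and reported.
#'
#' @param cohort labeled patient table, `n >= 3`.
#' @return list with `accuracy`, `sens`, `spec`, `calls` (per-fold
#'   data.frame with call, stage, label), and `n_skipped`.
#' @export
loocv <- function(cohort) {
  labels <- .check_labels(cohort$label)
  n <- nrow(cohort)
  if (n < 3L) stop("leave-one-out validation needs at least 3 patients")
  calls <- rep(NA_character_, n)
  stage <- rep(NA_integer_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    train <- cohort[-i, , drop = FALSE]
    if (length(unique(.check_labels(train$label))) < 2L) {
      skipped <- skipped + 1L
      warning("fold ", i, " skipped: single-class training set")
      next
    }
    cuts <- fit_cutoffs(train)
    st <- classify_sequential(cohort[i, , drop = FALSE], cuts)
    calls[i] <- st$call
    stage[i] <- st$stage
  }
  keep <- !is.na(calls)
  cm <- confusion(calls[keep], labels[keep])
  list(accuracy = cm$acc, sens = cm$sens, spec = cm$spec,
       calls = data.frame(call = calls, stage = stage, label = labels),
       n_skipped = skipped)
}

#' @export
print.flow_summary <- function(x, ...) {
  r2 <- function(v) format(round_half_out(v, 2), nsmall = 2)
  pct <- function(v) paste0(round_half_out(100 * v), "%")
  cat("Sequential PWI + PET classification flow\n")
  cat(sprintf("  cutoffs: rCBVmax > %.4g, TBRmax > %.4g, Slope < %.4g SUV/h\n",
              x$cutoffs$rcbv_cut, x$cutoffs$tbr_cut, x$cutoffs$slope_cut))
  cat(sprintf("  cohort                     n = %d\n", x$n_total))
  cat(sprintf("  stage 1: called TP         n = %d (spec %s, PPV %s)\n",
              x$n_stage1_tp, r2(x$stage1$spec), r2(x$stage1$ppv)))
  cat(sprintf("  stage 1: left unclassified n = %d\n", x$n_remaining))
  cat(sprintf("  stage 2: called TP         n = %d\n", x$n_stage2_tp))
  cat(sprintf("  stage 2: called TRC        n = %d", x$n_stage2_trc))
  if (!is.null(x$stage2))
    cat(sprintf("  (stage-2 acc %s, sens %s, NPV %s)",
                pct(x$stage2$acc), r2(x$stage2$sens), r2(x$stage2$npv)))
  cat("\n")
  cat(sprintf("  overall: acc %s, sens %s, spec %s\n",
              pct(x$overall$acc), pct(x$overall$sens), pct(x$overall$spec)))
  invisible(x)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  f <- function(nm) {
    v <- x[[nm]]
    ci <- x$ci95[[nm]]
    if (is.na(v)) return(sprintf("  %-4s undefined\n", nm))
    sprintf("  %-4s %.3f (95%% CI %.3f-%.3f)\n", nm, v, ci[1], ci[2])
  }
  for (nm in c("sens", "spec", "acc", "ppv", "npv")) cat(f(nm))
  invisible(x)
}

#' @export
print.cutoff_result <- function(x, ...) {
  op <- if (x$direction == "higher") ">" else "<"
  cat(sprintf("optimal cutoff: score %s %.4g (sens %.3f, spec %.3f, sens*spec %.3f)\n",
              op, x$cutoff, x$sens, x$spec, x$criterion_value))
  invisible(x)
}

#' @export
print.sequential_cutoffs <- function(x, ...) {
  cat(sprintf("sequential cutoffs: rCBVmax > %.4g; TBRmax > %.4g or Slope < %.4g SUV/h\n",
              x$rcbv_cut, x$tbr_cut, x$slope_cut))
  invisible(x)
}
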