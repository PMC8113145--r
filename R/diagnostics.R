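.check_labels <- function(labels) {
  labels <- toupper(trimws(as.character(labels)))
  bad <- setdiff(unique(labels), c("TP", "TRC"))
  if (length(bad))
    stop("labels must be TP or TRC; found: ", paste(bad, collapse = ", "))
  labels
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U comparison of two samples via midranks, with
#' exact enumeration for small tie-free samples (`n1 + n2 <= 12`) and the
#' tie-corrected normal approximation with continuity correction
#' otherwise (delegating to [stats::wilcox.test()]).  The reported `U`
#' counts pairs in which `x` exceeds `y` (ties count 1/2).
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = n1 * n2 / 2, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0L
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = (n1 + n2 <= 12L) && !ties, correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' ROC curve and AUC with DeLong inference
#'
#' Builds the ROC curve over candidate thresholds placed at midpoints
#' between consecutive distinct scores (plus infinite endpoints), with TP
#' as the positive class.  For `direction = "higher"` a score above the
#' threshold is called positive; for `"lower"` scores are negated
#' internally so that lower values are positive (e.g. the late PET
#' slope).  The AUC is the trapezoid area under the curve (identical to
#' the midrank Mann-Whitney `U / (n1*n2)`); its 95\% CI and two-sided p
#' value against 0.5 use the DeLong placement-value variance estimator.
#'
#' @param scores numeric parameter values.
#' @param labels TP/TRC per score (both classes must be present).
#' @param direction `"higher"` if larger scores indicate TP, else
#'   `"lower"`.
#' @return list with `curve` (a `roc_curve`: `thresholds` on the original
#'   scale, `sens`, `spec`, `direction`) and `auc` (an `auc_estimate`:
#'   `auc`, `ci95`, `p`, `var`).
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == "TP"
  if (!any(pos) || all(pos))
    stop("undefined AUC: both classes must be present")
  s <- if (direction == "lower") -scores else scores
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(s[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!pos] <= t), numeric(1))
  # trapezoid AUC in (FPR, TPR) space; thresholds ascending => FPR descending
  fpr <- 1 - spec
  auc <- -trapz(fpr, sens)  # negate: fpr runs from 1 down to 0
  # DeLong placement values
  xs <- s[pos]; ys <- s[!pos]
  n1 <- length(xs); n0 <- length(ys)
  d10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  d01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), numeric(1))
  v <- if (n1 > 1 && n0 > 1) var(d10) / n1 + var(d01) / n0 else NA_real_
  if (!is.na(v) && v > 0) {
    se <- sqrt(v)
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * se))
    p <- 2 * pnorm(-abs(auc - 0.5) / se)
  } else {
    ci <- c(auc, auc)
    p <- if (!is.na(v)) 0 else NA_real_
  }
  curve <- structure(list(
    thresholds = if (direction == "lower") -thr else thr,
    sens = sens, spec = spec, direction = direction),
    class = "roc_curve")
  est <- structure(list(auc = auc, ci95 = ci, p = p, var = v),
                   class = "auc_estimate")
  list(curve = curve, auc = est)
}

#' Optimal cutoff at the maximum product of sensitivity and specificity
#'
#' Scans the finite candidate thresholds of a ROC curve and returns the
#' one maximizing `sens * spec`.  Calls are strict: for a
#' higher-positive parameter a score above the cutoff is positive; for a
#' lower-positive parameter a score below it is.  Criterion ties break
#' toward higher specificity, then toward the lower cutoff value.
#'
#' @param curve a `roc_curve` from [roc_auc()].
#' @return a `cutoff_result` with `cutoff`, `sens`, `spec`,
#'   `criterion_value` and `direction`.
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fin <- is.finite(curve$thresholds)
  if (!any(fin)) stop("degenerate ROC curve: no finite thresholds")
  thr <- curve$thresholds[fin]
  sens <- curve$sens[fin]; spec <- curve$spec[fin]
  crit <- sens * spec
  ord <- order(-crit, -spec, thr)
  i <- ord[1]
  structure(list(cutoff = thr[i], sens = sens[i], spec = spec[i],
                 criterion_value = crit[i], direction = curve$direction),
            class = "cutoff_result")
}

.cp_ci <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(x, n)$conf.int)  # Clopper-Pearson exact
}

#' Confusion metrics with exact binomial confidence intervals
#'
#' Cross-tabulates diagnostic calls against ground-truth labels (TP
#' positive) and reports sensitivity, specificity, accuracy, PPV and NPV
#' with Clopper-Pearson 95\% intervals.  Rates with a zero denominator
#' are `NA` with no interval.
#'
#' @param calls,labels equal-length TP/TRC vectors.
#' @return a `confusion_metrics` object: counts `tp`, `fp`, `tn`, `fn`;
#'   rates `sens`, `spec`, `acc`, `ppv`, `npv`; `ci95` (named list of
#'   intervals).
#' @export
confusion <- function(calls, labels) {
  calls <- .check_labels(calls)
  labels <- .check_labels(labels)
  if (length(calls) != length(labels))
    stop("calls and labels must have equal length")
  tp <- sum(calls == "TP" & labels == "TP")
  fp <- sum(calls == "TP" & labels == "TRC")
  tn <- sum(calls == "TRC" & labels == "TRC")
  fn <- sum(calls == "TRC" & labels == "TP")
  rate <- function(x, n) if (n > 0) x / n else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sens = rate(tp, tp + fn), spec = rate(tn, tn + fp),
    acc = rate(tp + tn, tp + fp + tn + fn),
    ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
    ci95 = list(sens = .cp_ci(tp, tp + fn), spec = .cp_ci(tn, tn + fp),
                acc = .cp_ci(tp + tn, tp + fp + tn + fn),
                ppv = .cp_ci(tp, tp + fp), npv = .cp_ci(tn, tn + fn))),
    class = "confusion_metrics")
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_obs - p_exp) / (1 - p_exp)` with
#' marginal-product expected agreement.  When both raters are constant
#' and identical (`p_exp = 1`) kappa is defined as 1.
#'
#' @param calls_a,calls_b equal-length categorical vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  a <- as.character(calls_a); b <- as.character(calls_b)
  if (length(a) != length(b)) stop("rater sequences must have equal length")
  n <- length(a)
  if (n == 0L) stop("empty rater sequences")
  lev <- union(a, b)
  p_obs <- mean(a == b)
  p_exp <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (p_exp >= 1) return(1)
  (p_obs - p_exp) / (1 - p_exp)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  cor(x, y, method = "pearson")
}

#' Binormal two-class score simulation with a prescribed AUC
#'
#' Draws unit-variance normal scores for both classes with mean
#' separation `sqrt(2) * qnorm(auc)`, so the population AUC equals `auc`
#' exactly.  For `direction = "lower"` the positive (TP) class is shifted
#' downward instead of upward.
#'
#' @param auc target AUC in (0, 1).
#' @param n_tp,n_trc class sizes.
#' @param direction `"higher"` or `"lower"`.
#' @param seed integer RNG seed.
#' @return data.frame with columns `score` and `label`.
#' @export
gen_binormal_scores <- function(auc, n_tp, n_trc,
                                direction = c("higher", "lower"), seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(auc > 0, auc < 1, n_tp >= 1, n_trc >= 1)
  delta <- sqrt(2) * qnorm(auc)
  if (direction == "lower") delta <- -delta
  set.seed(seed)
  data.frame(score = c(rnorm(n_tp, mean = delta), rnorm(n_trc)),
             label = rep(c("TP", "TRC"), c(n_tp, n_trc)))
}

#' Per-parameter diagnostic performance table
#'
#' Computes, for each requested parameter of a patient table, the
#' class-wise median and unscaled MAD, the Mann-Whitney p value, the AUC
#' with DeLong CI and p, the sens*spec-optimal cutoff and its confusion
#' metrics — one row per parameter, mirroring a clinical performance
#' table.  Subgroups (e.g. by IDH status) are handled by filtering the
#' table before the call.
#'
#' @param cohort patient table with `label` and parameter columns.
#' @param parameters named character vector mapping column names to
#'   directions (`"higher"`/`"lower"`).
#' @return data.frame, one row per parameter.
#' @export
cohort_performance <- function(cohort,
                               parameters = c(rCBV_max = "higher",
                                              TBR_max = "higher",
                                              TBR_mean = "higher",
                                              Slope_suv_per_h = "lower",
                                              TTP_min = "higher")) {
  labels <- .check_labels(cohort$label)
  umad <- function(v) median(abs(v - median(v)))
  rows <- lapply(names(parameters), function(p) {
    v <- cohort[[p]]
    if (is.null(v)) stop("cohort lacks parameter column ", p)
    dirn <- parameters[[p]]
    mw <- mann_whitney(v[labels == "TP"], v[labels == "TRC"])
    ra <- roc_auc(v, labels, dirn)
    # a constant parameter has no finite candidate threshold; report it
    # with an undefined cutoff block rather than failing the whole table
    co <- tryCatch(optimal_cutoff(ra$curve), error = function(e) NULL)
    if (is.null(co)) {
      co <- list(cutoff = NA_real_)
      cm <- list(sens = NA_real_, spec = NA_real_, acc = NA_real_,
                 ppv = NA_real_, npv = NA_real_)
    } else {
      calls <- classify_threshold(v, co$cutoff, dirn)
      cm <- confusion(calls, labels)
    }
    data.frame(parameter = p, direction = dirn,
               median_tp = median(v[labels == "TP"]),
               mad_tp = umad(v[labels == "TP"]),
               median_trc = median(v[labels == "TRC"]),
               mad_trc = umad(v[labels == "TRC"]),
               p_mw = mw$p, auc = ra$auc$auc,
               auc_lo = ra$auc$ci95[1], auc_hi = ra$auc$ci95[2],
               p_auc = ra$auc$p, cutoff = co$cutoff,
               sens = cm$sens, spec = cm$spec, acc = cm$acc,
               ppv = cm$ppv, npv = cm$npv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold a parameter into TP/TRC calls
#'
#' Strict-inequality call rule: for `direction = "higher"`, TP when the
#' score exceeds the cutoff; for `"lower"`, TP when it falls below.
#'
#' @param scores numeric values.
#' @param cutoff threshold.
#' @param direction `"higher"` or `"lower"`.
#' @return character vector of TP/TRC calls.
#' @export
classify_threshold <- function(scores, cutoff,
                               direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  pos <- if (direction == "higher") scores > cutoff else scores < cutoff
  ifelse(pos, "TP", "TRC")
}
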