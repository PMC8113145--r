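#' Dynamic susceptibility contrast signal series
#'
#' A per-ROI (or per-voxel) DSC signal-time course together with its
#' acquisition settings.
#'
#' @param times frame times in seconds, strictly increasing.
#' @param signal scanner-unit signal per frame.
#' @param acquisition a [dsc_acquisition()].
#' @return a `dsc_series` object.
#' @export
dsc_series <- function(times, signal, acquisition) {
  stopifnot(inherits(acquisition, "dsc_acquisition"),
            length(times) == length(signal),
            length(times) == acquisition$n_frames)
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 acquisition = acquisition),
            class = "dsc_series")
}

delta_r2_series <- function(times, values, acquisition) {
  structure(list(times = times, values = values, acquisition = acquisition),
            class = "delta_r2_series")
}

#' Convert a DSC signal curve to a delta-R2* curve
#'
#' Baseline-referenced transverse relaxivity change,
#' `dR2*(t) = -log(S(t)/S0) / TE`, with `S0` the mean signal over the
#' pre-bolus baseline window.  Baseline frames average to zero by
#' construction (exactly so at zero noise), and the result is invariant
#' to a global rescaling of the signal.
#'
#' @param series a [dsc_series()].
#' @return a `delta_r2_series` (times in seconds, values in 1/s).
#' @export
delta_r2star <- function(series) {
  stopifnot(inherits(series, "dsc_series"))
  bad <- which(series$signal <= 0)
  if (length(bad))
    stop("nonpositive signal at frame(s) ", paste(bad, collapse = ", "),
         "; cannot take the log")
  acq <- series$acquisition
  s0 <- mean(series$signal[acq$baseline])
  delta_r2_series(series$times, -log(series$signal / s0) / acq$te, acq)
}

#' Average delta-R2* curves into a reference bolus
#'
#' Pointwise arithmetic mean over the included curves; the
#' Boxerman-Weisskoff correction uses the average over nonenhancing
#' tissue as its reference.
#'
#' @param series_set list of `delta_r2_series` on a common time grid.
#' @param include logical inclusion flags (default: all).
#' @return a `delta_r2_series`.
#' @export
reference_curve <- function(series_set, include = NULL) {
  include <- include %||% rep(TRUE, length(series_set))
  stopifnot(length(include) == length(series_set))
  kept <- series_set[include]
  if (!length(kept)) stop("reference_curve: no series included")
  t0 <- kept[[1]]$times
  for (s in kept)
    if (!isTRUE(all.equal(s$times, t0)))
      stop("all series must share one time grid")
  vals <- rowMeans(vapply(kept, `[[`, numeric(length(t0)), "values"))
  delta_r2_series(t0, vals, kept[[1]]$acquisition)
}

#' Boxerman-Weisskoff leakage fit
#'
#' Models the tumor delta-R2* curve as
#' `target(t) = k1 * reference(t) - k2 * R(t)`, where `R(t)` is the
#' running trapezoid integral of the reference from the first frame
#' (`R = 0` there).  `k1` and `k2` come from closed-form linear least
#' squares; the leakage-corrected curve adds the extravasation term back:
#' `corrected(t) = target(t) + k2 * R(t)`.  Positive `k2` (T1-dominant
#' leakage) depresses the measured curve, so correction restores lost
#' blood-volume area.
#'
#' @param target,reference `delta_r2_series` on identical time grids.
#' @return a `leakage_fit` with `k1`, `k2` (1/s), `corrected`
#'   (`delta_r2_series`) and `residual_sse`.
#' @export
bw_fit <- function(target, reference) {
  stopifnot(inherits(target, "delta_r2_series"),
            inherits(reference, "delta_r2_series"))
  if (!isTRUE(all.equal(target$times, reference$times)))
    stop("target and reference must share one time grid")
  if (all(reference$values == 0))
    stop("degenerate fit: reference is identically zero")
  R <- cumtrapz(reference$times, reference$values)
  X <- cbind(reference$values, -R)
  qx <- qr(X)
  if (qx$rank < 2L)
    stop("degenerate fit: reference and its running integral are collinear")
  beta <- qr.coef(qx, target$values)
  k1 <- unname(beta[1]); k2 <- unname(beta[2])
  corrected <- target$values + k2 * R
  res <- target$values - (k1 * reference$values - k2 * R)
  structure(list(k1 = k1, k2 = k2,
                 corrected = delta_r2_series(target$times, corrected,
                                             target$acquisition),
                 residual_sse = sum(res^2)),
            class = "leakage_fit")
}

#' Integrate a delta-R2* curve into a blood-volume area
#'
#' Trapezoidal integral of the curve over a frame window; negative values
#' enter as-is (no clipping).  The default window is the whole
#' post-baseline acquisition, matching whole-curve CBV integration.
#'
#' @param curve a `delta_r2_series`.
#' @param window integer frame indices (1-based); default all frames after
#'   the acquisition's baseline window.
#' @return the area (dimensionless, 1/s times s).
#' @export
cbv_integrate <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "delta_r2_series"))
  n <- length(curve$times)
  window <- window %||% setdiff(seq_len(n), curve$acquisition$baseline)
  if (length(window) < 2L) stop("integration window must span at least 2 frames")
  if (min(window) < 1L || max(window) > n)
    stop("integration window outside the series")
  trapz(curve$times[window], curve$values[window])
}

#' Hotspot rCBVmax from per-voxel CBV values
#'
#' Emulates hotspot ROI reading of a CBV map: the tumor value is the mean
#' of the `k` largest CBV areas inside the tumor mask (the "area of
#' maximum CBV"), the reference value is the mean over an equally sized
#' contralateral normal-appearing ROI (its `k` voxels taken in fixed index
#' order, not by magnitude), and `rcbv_max` is their ratio.
#'
#' @param cbv_values numeric vector (or array) of per-voxel CBV areas.
#' @param tumor_mask,contralateral_mask logical masks of the same length;
#'   they must not overlap and must each contain at least `k` voxels.
#' @param k hotspot size in voxels (default 10).
#' @return a `cbv_result` with `cbv_tumor`, `cbv_reference`, `rcbv_max`.
#' @export
#' @examples
#' hotspot_rcbv(c(1, 1, 5, 5, 2, 2, 2, 2),
#'              c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
#'              c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
#'              k = 2)$rcbv_max  # 2.5
hotspot_rcbv <- function(cbv_values, tumor_mask, contralateral_mask, k = 10L) {
  cbv_values <- as.numeric(cbv_values)
  tumor_mask <- as.logical(tumor_mask)
  contralateral_mask <- as.logical(contralateral_mask)
  stopifnot(length(tumor_mask) == length(cbv_values),
            length(contralateral_mask) == length(cbv_values), k >= 1L)
  if (any(tumor_mask & contralateral_mask))
    stop("tumor and contralateral masks overlap")
  if (sum(tumor_mask) < k) stop("tumor mask smaller than hotspot size k")
  if (sum(contralateral_mask) < k)
    stop("contralateral mask smaller than hotspot size k")
  tum <- sort(cbv_values[tumor_mask], decreasing = TRUE)[seq_len(k)]
  ref <- cbv_values[contralateral_mask][seq_len(k)]
  cbv_reference <- mean(ref)
  if (cbv_reference <= 0)
    stop("non-physical reference: contralateral CBV must be positive")
  structure(list(cbv_tumor = mean(tum), cbv_reference = cbv_reference,
                 rcbv_max = mean(tum) / cbv_reference),
            class = "cbv_result")
}

#' ROI-level leakage-corrected rCBV from a tumor/reference signal pair
#'
#' Full DSC pipeline on two ROI signal curves: convert both to delta-R2*,
#' fit the Boxerman-Weisskoff leakage model of the tumor against the
#' reference, integrate the corrected tumor curve and the reference curve
#' over the post-baseline window, and form the ratio.
#'
#' @param tumor,reference [dsc_series()] on a common grid.
#' @return a `cbv_result` (as [hotspot_rcbv()]) with the `leakage_fit`
#'   attached as element `fit`.
#' @export
rcbv_roi <- function(tumor, reference) {
  tum_r2 <- delta_r2star(tumor)
  ref_r2 <- delta_r2star(reference)
  fit <- bw_fit(tum_r2, ref_r2)
  cbv_tumor <- cbv_integrate(fit$corrected)
  cbv_reference <- cbv_integrate(ref_r2)
  if (cbv_reference <= 0)
    stop("non-physical reference: contralateral CBV must be positive")
  structure(list(cbv_tumor = cbv_tumor, cbv_reference = cbv_reference,
                 rcbv_max = cbv_tumor / cbv_reference, fit = fit),
            class = "cbv_result")
}
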