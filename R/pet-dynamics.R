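#' PET time-activity curve
#'
#' ROI-level dynamic amino-acid PET data: frame mid-times with tumor mean,
#' tumor maximum and background mean activity concentrations, plus the
#' dose and weight needed for SUV scaling.
#'
#' @param frame_mid_times minutes post-injection, strictly increasing.
#' @param tumor_mean,tumor_max,background_mean activity concentration
#'   (Bq/g) per frame.
#' @param weight_g patient weight in grams (> 0).
#' @param injected_bq injected activity in Bq (> 0).
#' @return a `tac` object.
#' @export
tac <- function(frame_mid_times, tumor_mean, tumor_max, background_mean,
                weight_g, injected_bq) {
  n <- length(frame_mid_times)
  stopifnot(length(tumor_mean) == n, length(tumor_max) == n,
            length(background_mean) == n)
  if (any(diff(frame_mid_times) <= 0))
    stop("frame mid-times must be strictly increasing")
  if (weight_g <= 0) stop("patient weight must be positive")
  if (injected_bq <= 0) stop("injected activity must be positive")
  structure(list(frame_mid_times = as.numeric(frame_mid_times),
                 tumor_mean = as.numeric(tumor_mean),
                 tumor_max = as.numeric(tumor_max),
                 background_mean = as.numeric(background_mean),
                 weight_g = weight_g, injected_bq = injected_bq),
            class = "tac")
}

#' Standardized uptake value
#'
#' `SUV = activity concentration [Bq/g] * patient weight [g] /
#' injected activity [Bq]`; dimensionless, linear in concentration.
#'
#' @param activity_concentration Bq/g.
#' @param weight_g patient weight in grams (> 0).
#' @param injected_bq injected activity in Bq (> 0).
#' @return SUV (same shape as `activity_concentration`).
#' @export
#' @examples
#' suv(1500, 75000, 180e6)  # 0.625
suv <- function(activity_concentration, weight_g, injected_bq) {
  if (weight_g <= 0) stop("patient weight must be positive")
  if (injected_bq <= 0) stop("injected activity must be positive")
  activity_concentration * weight_g / injected_bq
}

.window_frames <- function(tac, window) {
  which(tac$frame_mid_times >= window[1] & tac$frame_mid_times <= window[2])
}

#' Tumor-to-brain ratios
#'
#' Frame-averaged tumor SUV divided by frame-averaged background SUV over
#' the evaluation window (default 20-40 min, the late uptake period used
#' for static FET reading); `tbr_mean` uses the tumor mean curve,
#' `tbr_max` the tumor maximum curve.  The dose/weight scaling cancels in
#' the ratio.
#'
#' @param tac a [tac()].
#' @param window evaluation window in minutes (inclusive).
#' @return list with `tbr_mean` and `tbr_max`.
#' @export
tbr <- function(tac, window = c(20, 40)) {
  stopifnot(inherits(tac, "tac"))
  idx <- .window_frames(tac, window)
  if (!length(idx)) stop("no frames inside the evaluation window")
  bg <- mean(tac$background_mean[idx])
  if (bg <= 0) stop("background activity must be positive in the window")
  list(tbr_mean = mean(tac$tumor_mean[idx]) / bg,
       tbr_max = mean(tac$tumor_max[idx]) / bg)
}

#' Time-to-peak of the tumor time-activity curve
#'
#' Frame mid-time (minutes) at which the tumor mean curve attains its
#' maximum; ties resolve to the earliest frame.
#'
#' @param tac a [tac()].
#' @return minutes post-injection.
#' @export
ttp <- function(tac) {
  stopifnot(inherits(tac, "tac"))
  if (length(tac$frame_mid_times) < 2L) stop("need at least 2 frames")
  tac$frame_mid_times[which.max(tac$tumor_mean)]
}

#' Late slope of the tumor time-activity curve
#'
#' Ordinary-least-squares slope of the tumor mean SUV against frame
#' mid-time over the 20-40 min window (frames weighted equally),
#' expressed in SUV per hour.  Low or negative values (washout) point to
#' tumor progression; rising curves to treatment-related changes.
#'
#' @param tac a [tac()].
#' @param window slope window in minutes (inclusive; default 20-40).
#' @return slope in SUV/h.
#' @export
slope_20_40 <- function(tac, window = c(20, 40)) {
  stopifnot(inherits(tac, "tac"))
  idx <- .window_frames(tac, window)
  if (length(idx) < 2L)
    stop("insufficient frames: need at least 2 frame mid-times in [",
         window[1], ", ", window[2], "] min")
  t_min <- tac$frame_mid_times[idx]
  y <- suv(tac$tumor_mean[idx], tac$weight_g, tac$injected_bq)
  unname(coef(lm(y ~ t_min))[2]) * 60
}

#' All PET parameters from one time-activity curve
#'
#' @param tac a [tac()].
#' @param window evaluation/slope window in minutes.
#' @return list with `tbr_mean`, `tbr_max`, `ttp` (min), `slope` (SUV/h).
#' @export
pet_params <- function(tac, window = c(20, 40)) {
  r <- tbr(tac, window)
  list(tbr_mean = r$tbr_mean, tbr_max = r$tbr_max, ttp = ttp(tac),
       slope = slope_20_40(tac, window))
}
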