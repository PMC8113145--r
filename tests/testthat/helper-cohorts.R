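# shared in-code fixtures for the classifier tests

# perfectly separated two-class table: every parameter splits the classes
separated_cohort <- function(n_tp = 10, n_trc = 6) {
  data.frame(
    patient_id = sprintf("S%02d", seq_len(n_tp + n_trc)),
    label = rep(c("TP", "TRC"), c(n_tp, n_trc)),
    rCBV_max = c(seq(3.0, 4.0, length.out = n_tp),
                 seq(1.5, 2.2, length.out = n_trc)),
    TBR_max = c(seq(2.1, 2.6, length.out = n_tp),
                seq(1.4, 1.8, length.out = n_trc)),
    TBR_mean = c(seq(1.9, 2.3, length.out = n_tp),
                 seq(1.3, 1.7, length.out = n_trc)),
    Slope_suv_per_h = c(seq(-0.5, 0.3, length.out = n_tp),
                        seq(0.8, 1.4, length.out = n_trc)),
    TTP_min = 32.5, idh_status = "wildtype", group = "all")
}

# random labelled score set for ROC property checks
random_roc_instance <- function(n_tp, n_trc, ties = FALSE) {
  score <- if (ties) sample(1:5, n_tp + n_trc, replace = TRUE)
           else rnorm(n_tp + n_trc)
  list(scores = score, labels = rep(c("TP", "TRC"), c(n_tp, n_trc)))
}

# midrank Mann-Whitney U of TP scores over TRC scores (rank-sum identity),
# independent of the ROC code path
u_midrank <- function(scores, labels) {
  pos <- labels == "TP"
  r <- rank(scores)
  sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2
}
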