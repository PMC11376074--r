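# Build an alkane_profile directly, bypassing peak detection, for rule tests.
# residual_alkanes = number of non-nC17/nC18 alkane peaks present.
make_profile <- function(c17_pr = NA_real_, c18_ph = NA_real_,
                         dominance = NA_real_,
                         residual_alkanes = 0L,
                         include_c17_c18 = TRUE) {
  assignments <- c(if (include_c17_c18) c("nC17", "nC18"),
                   if (residual_alkanes > 0)
                     paste0("nC", seq(20, by = 1,
                                      length.out = residual_alkanes)))
  peaks <- data.frame(apex_rt = seq_along(assignments) + 0,
                      height = rep(1, length(assignments)),
                      area = rep(1, length(assignments)),
                      assignment = as.character(assignments),
                      stringsAsFactors = FALSE)
  structure(list(peaks = peaks, c17_pr_ratio = c17_pr,
                 c18_ph_ratio = c18_ph,
                 n_alkanes_present = nrow(peaks),
                 pr_ph_dominance = dominance),
            class = "alkane_profile")
}
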