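# Builders for small hand-made round tables.

make_rounds <- function(subject_id, round_index, n1_sbp, n1_dbp, n2_sbp,
                        n2_dbp, dev_status = "ok", dev_sbp = NA_real_,
                        dev_dbp = NA_real_) {
  df <- data.frame(subject_id = subject_id, round_index = round_index,
                   n1_sbp = n1_sbp, n1_dbp = n1_dbp,
                   n2_sbp = n2_sbp, n2_dbp = n2_dbp,
                   dev_status = dev_status, dev_sbp = dev_sbp,
                   dev_dbp = dev_dbp, stringsAsFactors = FALSE)
  # default device reading mirrors nurse 1 when the status is ok
  ok <- df$dev_status == "ok"
  df$dev_sbp[ok & is.na(df$dev_sbp)] <- df$n1_sbp[ok & is.na(df$dev_sbp)]
  df$dev_dbp[ok & is.na(df$dev_dbp)] <- df$n1_dbp[ok & is.na(df$dev_dbp)]
  df
}

# n rounds of perfectly agreeing readings for one subject
stable_subject <- function(subject_id, n = 4, sbp = 120, dbp = 80) {
  make_rounds(subject_id = rep(subject_id, n), round_index = seq_len(n),
              n1_sbp = sbp, n1_dbp = dbp, n2_sbp = sbp, n2_dbp = dbp)
}

# embed retained pairs back into the round layout (both nurses read the
# reference, device ok) so the cascade can be re-applied
pairs_to_rounds <- function(pairs) {
  make_rounds(subject_id = pairs$subject_id,
              round_index = pairs$round_index,
              n1_sbp = pairs$reference_sbp, n1_dbp = pairs$reference_dbp,
              n2_sbp = pairs$reference_sbp, n2_dbp = pairs$reference_dbp,
              dev_status = "ok", dev_sbp = pairs$device_sbp,
              dev_dbp = pairs$device_dbp)
}

# vector with exact mean m and sample SD s
sample_with_stats <- function(m, s, n = 9) {
  base <- seq_len(n)
  base <- (base - mean(base)) / stats::sd(base)
  m + s * base
}
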