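# internal helpers / NSE hygiene

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "bird_id", "antenna_id", "timestamp", "prev_ant",
  "bout", "feeder_id", "start", "end", "duration_s", "n_records",
  "close_reason", "age_days", "nfv", "mfbd_s", "ndf", "total_feeding_s",
  "complete", "sex", "bw_14", "bw_35", "gait_27", "gait_score_27",
  "gait_class", "start_bw_g", "bw_gain_g_d", "val", "y", "ts",
  "x0", "x1", "feeder", "value", "descriptor", "comp", "t", "bird", "ant"))
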