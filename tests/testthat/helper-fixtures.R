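# shared fixtures: everything is generated in code at test time

make_trace <- function(values, rate_hz = 10, channel = "470", roi = "Region0") {
  photometry_trace((seq_along(values) - 1) / rate_hz, values,
                   channel = channel, roi = roi, rate_hz = rate_hz)
}

make_track <- function(mobility, rate_hz = 10) {
  behavior_track((seq_along(mobility) - 1) / rate_hz, mobility,
                 rate_hz = rate_hz)
}

# a short session small enough for unit tests
small_config <- function(...) {
  args <- utils::modifyList(list(duration_s = 120, seed = 42L), list(...))
  do.call(synth_config, args)
}

# interleaved frame CSV fixture written to a temp file
write_frame_csv <- function(path, n = 6, codes = c(1L, 2L),
                            timestamps = NULL, drop_col = NULL) {
  df <- data.frame(FrameCounter = seq_len(n) - 1L,
                   Timestamp = timestamps %||% ((seq_len(n) - 1) / 20),
                   LedState = rep_len(codes, n),
                   Region0 = seq_len(n) + 0.5)
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# dense uniform-weight Whittaker solve: the independent baseline oracle
whittaker_uniform_oracle <- function(y, lambda) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  as.numeric(solve(diag(n) + lambda * crossprod(D), y))
}

# match a zdff trace onto ground-truth signal-channel samples by timestamp
gt_index <- function(zdff, gt_trace) {
  match(sprintf("%.6f", zdff$time_s), sprintf("%.6f", gt_trace$time_s))
}
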