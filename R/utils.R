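# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

ff_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fiberflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ff_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "fiberflow_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs code as-is.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    ff_stop("ff_param_error", "'%s' must not be NULL", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ff_stop("ff_param_error", "'%s' must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    ff_stop("ff_param_error", "'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    ff_stop("ff_param_error", "'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    ff_stop("ff_param_error", "'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Pearson r with two-sided t-test p-value; returns list(r, p, n).
pearson_rp <- function(x, y) {
  n <- length(x)
  if (n < 3L) ff_stop("ff_data_error", "need >= 3 paired samples, got %d", n)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n, degenerate = FALSE)
}

# Linear interpolation of a trace-like (time, value) onto new times; errors
# when extrapolation would be required.
interp_at <- function(time_s, value, at) {
  if (min(at) < time_s[1L] - 1e-9 || max(at) > time_s[length(time_s)] + 1e-9)
    ff_stop("ff_range_error", "requested times outside the trace support")
  stats::approx(time_s, value, xout = at, rule = 2)$y
}

# deterministic number formatting used by all CSV writers so reruns are
# byte-identical
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.12g", v)
  }, character(1))
  out
}

write_table_deterministic <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(
    paste(names(df), collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  if (nrow(df) == 0L) lines <- lines[1L]
  writeLines(lines, path)
}
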