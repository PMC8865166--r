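# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-participant substream: depends only on (seed, index) so cohorts are
# reproducible under reordering. Kept well below 2^31.
substream_seed <- function(seed, index, salt = 0L) {
  (abs(as.integer(seed)) + 7919L * as.integer(index) + 104729L * as.integer(salt)) %% 2147483629L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sampling rate from a uniform time grid; errors if spacing is not uniform
# to within 1 ppm
infer_fs <- function(time_s) {
  if (length(time_s) < 2) abort("need at least two samples to infer a sampling rate")
  dt <- diff(time_s)
  m <- median(dt)
  if (m <= 0 || any(abs(dt - m) > 1e-6 * m + 1e-12)) {
    abort("time grid is not uniform (spacing varies by more than 1 ppm)")
  }
  1 / m
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lo, hi))
  }
  invisible(x)
}

# deterministic TSV writer used for every emitted table (fixed formatting so
# identical inputs give identical bytes)
write_tsv_det <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, format = "g", digits = 12))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

read_tsv_det <- function(path) {
  as_tibble(read.delim(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, check.names = FALSE))
}

log_msg <- function(..., level = "INFO", verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", level, sprintf(...)))
  }
  invisible(NULL)
}
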