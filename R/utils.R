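#' @include AllClasses.R
NULL

# Timestamps are naive local time carried in UTC POSIXct (the study window is
# assumed DST-free); no timezone arithmetic anywhere.
.parse_time <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(as.character(x), tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"),
                    optional = TRUE)
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("unparseable %s at row %d: '%s'", what, bad[1], x[bad[1]]))
  out
}

.local_date <- function(t) as.Date(t, tz = "UTC")

.midnight <- function(d) as.POSIXct(paste(format(d), "00:00:00"), tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministic, collision-scattered derivation of per-stage RNG seeds from
#' one master seed (the pipeline's splittable-seed scheme). Every derived
#' seed is a valid 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param stage stage label (any string).
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

# Split-chain potential scale reduction (Rhat) for a single chain of draws.
splitRhat <- function(x) {
  m <- length(x)
  if (m < 4L || sd(x) == 0) return(NA_real_)
  half <- floor(m / 2)
  chains <- cbind(x[seq_len(half)], x[(m - half + 1):m])
  n <- nrow(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}
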