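#' @include utils.R
NULL

#' Read an acoustic detection series
#'
#' Reads a CSV of acoustic detections (columns `fish_id`, `timestamp`;
#' additional columns such as `receiver_id` are ignored), parses and sorts
#' the timestamps within fish, and collapses exact duplicate
#' (fish, timestamp) rows with a warning.
#'
#' @param path path to the CSV file, or a data.frame already in memory.
#' @return a data.frame (fish_id, timestamp) ordered by fish and time, the
#'   package's detection-series layout.
#' @export
readDetections <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  .assert_cols(df, c("fish_id", "timestamp"), "detections")
  out <- data.frame(fish_id = as.character(df$fish_id),
                    timestamp = .parse_time(df$timestamp),
                    stringsAsFactors = FALSE)
  out <- out[order(out$fish_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(out[c("fish_id", "timestamp")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (fish, timestamp) detections",
                    sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a sun table
#'
#' Reads a CSV with columns `date`, `sunrise`, `sunset` (local datetimes) and
#' validates that sunrise precedes sunset on every day.
#'
#' @param path path to the CSV file, or a data.frame.
#' @return a data.frame (date, sunrise, sunset).
#' @export
readSunTable <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  .assert_cols(df, c("date", "sunrise", "sunset"), "sun table")
  out <- data.frame(date = as.Date(df$date),
                    sunrise = .parse_time(df$sunrise, "sunrise"),
                    sunset = .parse_time(df$sunset, "sunset"))
  if (any(out$sunrise >= out$sunset))
    stop("sun table has sunrise >= sunset on ",
         format(out$date[which(out$sunrise >= out$sunset)[1]]))
  out[order(out$date), , drop = FALSE]
}

#' Read fish metadata
#'
#' Reads the per-fish covariate table: `fish_id`, `length` (mm), `sex`,
#' `year`, `tag_date` and home-range centre coordinates `centre_easting`,
#' `centre_northing` (planar metres).
#'
#' @param path path to the CSV file, or a data.frame.
#' @return a data.frame with one row per fish; `sex` and `year` as factors.
#' @export
readFishMeta <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  .assert_cols(df, c("fish_id", "length", "sex", "year", "tag_date",
                     "centre_easting", "centre_northing"), "fish metadata")
  if (anyDuplicated(df$fish_id))
    stop("fish metadata must have one row per fish")
  df$fish_id <- as.character(df$fish_id)
  df$sex <- factor(df$sex)
  df$year <- factor(df$year)
  df$tag_date <- as.Date(df$tag_date)
  df
}

#' Clean a detection series
#'
#' Applies the two cleaning rules used on the tracking data: (i) a per-fish
#' post-tagging discard window, dropping detections recorded during the
#' abnormal-behaviour period after tagging, and (ii) removal of spurious
#' (isolated) detections — any detection with fewer than `spuriousK` other
#' detections of the same fish in the surrounding 24 h. The spurious rule is
#' iterated to a fixed point, so cleaning is idempotent.
#'
#' @param series detection series from [readDetections()].
#' @param discardDays length of the post-tagging discard window in days
#'   (default 2).
#' @param spuriousK minimum number of companion detections required in the
#'   surrounding 24 h (default 2).
#' @param tagDates optional named vector/Date of tag dates per fish (or a
#'   metadata data.frame with `fish_id` and `tag_date`); when absent each
#'   fish's first detection marks its tagging time.
#' @return the cleaned series, with a `cleaning` attribute listing the number
#'   of detections removed by each rule.
#' @export
cleanDetections <- function(series, discardDays = 2, spuriousK = 2,
                            tagDates = NULL) {
  .assert_cols(series, c("fish_id", "timestamp"), "detections")
  if (is.data.frame(tagDates)) {
    tagDates <- setNames(as.Date(tagDates$tag_date), tagDates$fish_id)
  }
  removed_discard <- 0L
  removed_spurious <- 0L
  keep <- vector("list", 0L)
  for (id in unique(series$fish_id)) {
    ts <- series$timestamp[series$fish_id == id]
    ts <- sort(ts)
    t0 <- if (!is.null(tagDates) && id %in% names(tagDates))
      .midnight(tagDates[[id]]) else ts[1]
    cut <- t0 + discardDays * 86400
    removed_discard <- removed_discard + sum(ts < cut)
    ts <- ts[ts >= cut]
    # iterate the isolation rule to a fixed point
    repeat {
      if (!length(ts)) break
      tn <- as.numeric(ts)
      lo <- findInterval(tn - 43200, tn)        # index of last value < t-12h
      hi <- findInterval(tn + 43200, tn)
      companions <- hi - lo - 1L                # others within +-12 h
      iso <- companions < spuriousK
      if (!any(iso)) break
      removed_spurious <- removed_spurious + sum(iso)
      ts <- ts[!iso]
    }
    if (length(ts))
      keep[[id]] <- data.frame(fish_id = id, timestamp = ts,
                               stringsAsFactors = FALSE)
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    series[0, c("fish_id", "timestamp")]
  rownames(out) <- NULL
  if (!nrow(out)) warning("cleaning removed every detection")
  attr(out, "cleaning") <- list(removed_discard = removed_discard,
                                removed_spurious = removed_spurious)
  out
}

#' Bin a detection series into a 5-min Markovian chain
#'
#' Pools the detections of one fish into contiguous fixed-width bins
#' (half-open intervals `[start, start + bin)`), spanning whole local days
#' from the midnight before the first detection to the midnight after the
#' last. Bins with no detections get count 0, never NA.
#'
#' @param series cleaned detection series for a single fish.
#' @param binMinutes bin width in minutes (default 5).
#' @return a data.frame (fish_id, bin_start, count) with attribute
#'   `binMinutes`; the hidden Markov model's observation chain.
#' @export
binDetections <- function(series, binMinutes = 5) {
  .assert_cols(series, c("fish_id", "timestamp"), "detections")
  if (!nrow(series)) stop("no detections to bin")
  ids <- unique(series$fish_id)
  if (length(ids) != 1L)
    stop("binDetections expects a single fish; got ", length(ids))
  ts <- sort(series$timestamp)
  start <- .midnight(.local_date(ts[1]))
  end <- .midnight(.local_date(ts[length(ts)]) + 1L)
  step <- binMinutes * 60
  nb <- as.integer(round((as.numeric(end) - as.numeric(start)) / step))
  # epoch arithmetic keeps bin boundaries exact (half-open [start, start+bin))
  idx <- floor((as.numeric(ts) - as.numeric(start)) / step) + 1L
  counts <- tabulate(idx, nbins = nb)
  chain <- data.frame(fish_id = ids,
                      bin_start = start + (seq_len(nb) - 1L) * step,
                      count = as.integer(counts),
                      stringsAsFactors = FALSE)
  attr(chain, "binMinutes") <- binMinutes
  chain
}

#' Partition a binned chain into day views with sun times
#'
#' Splits a binned chain at local midnights and attaches each day's sunrise
#' and sunset from the sun table.
#'
#' @param chain binned chain from [binDetections()].
#' @param sunTable sun table from [readSunTable()].
#' @return a named list (one element per date) of lists with `date`,
#'   `sunrise`, `sunset` and the day's `bins`.
#' @export
alignDays <- function(chain, sunTable) {
  .assert_cols(chain, c("fish_id", "bin_start", "count"), "binned chain")
  dates <- .local_date(chain$bin_start)
  missing <- setdiff(format(unique(dates)), format(sunTable$date))
  if (length(missing))
    stop("sun table is missing date(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(seq_len(nrow(chain)), dates), function(ix) {
    d <- dates[ix[1]]
    row <- match(d, sunTable$date)
    list(date = d, sunrise = sunTable$sunrise[row],
         sunset = sunTable$sunset[row],
         bins = chain[ix, , drop = FALSE])
  })
  out
}
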