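#' @include hmm.R
NULL

.runs <- function(state) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L, end = ends)
}

# Optional minimum-bout filter: active runs shorter than minBout bins are
# relabelled rest. Off (minBout = 1) by default — isolated decoded active
# bins are kept as decoded.
.filter_bouts <- function(state, minBout) {
  if (minBout <= 1L) return(state)
  runs <- .runs(state)
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] == "active" && (runs$end[i] - runs$start[i] + 1L) < minBout)
      state[runs$start[i]:runs$end[i]] <- "rest"
  }
  state
}

#' Awakening time relative to sunrise
#'
#' The start time of the first active bin of the day, minus sunrise, in
#' signed minutes (negative = pre-dawn activity).
#'
#' @param dayView data.frame of one day's bins with columns `bin_start` and
#'   `state` ("active"/"rest").
#' @param sunrise the day's sunrise (POSIXct).
#' @return signed minutes, or NA when the day has no active bin.
#' @export
awakeningTime <- function(dayView, sunrise) {
  act <- which(dayView$state == "active")
  if (!length(act)) return(NA_real_)
  as.numeric(dayView$bin_start[act[1]] - sunrise, units = "mins")
}

#' Rest onset relative to sunset
#'
#' The end time of the last active bin of the day (the moment activity
#' ceases), minus sunset, in signed minutes.
#'
#' @param dayView data.frame of one day's bins with columns `bin_start`,
#'   `state`, and bin width taken from the `binMinutes` attribute (default 5).
#' @param sunset the day's sunset (POSIXct).
#' @param binMinutes bin width in minutes.
#' @return signed minutes, or NA when the day has no active bin.
#' @export
restOnset <- function(dayView, sunset, binMinutes = attr(dayView, "binMinutes") %||% 5) {
  act <- which(dayView$state == "active")
  if (!length(act)) return(NA_real_)
  lastEnd <- dayView$bin_start[act[length(act)]] + binMinutes * 60
  as.numeric(lastEnd - sunset, units = "mins")
}

#' Rest duration
#'
#' Time from the previous day's rest onset to the current day's awakening,
#' in decimal hours.
#'
#' @param prevOnsetAbs absolute clock time of the previous day's rest onset.
#' @param awakeningAbs absolute clock time of the current day's awakening.
#' @return decimal hours; NA with a warning when the ordering is violated.
#' @export
restDuration <- function(prevOnsetAbs, awakeningAbs) {
  if (is.na(prevOnsetAbs) || is.na(awakeningAbs)) return(NA_real_)
  if (awakeningAbs <= prevOnsetAbs) {
    warning("awakening precedes the previous rest onset; rest duration invalid")
    return(NA_real_)
  }
  as.numeric(awakeningAbs - prevOnsetAbs, units = "hours")
}

#' Build the daily trait table
#'
#' Converts decoded state sequences plus the sun table into one row per
#' fish-day of the circadian traits: awakening time (min relative to
#' sunrise), rest onset (min relative to sunset) and rest duration (h,
#' previous onset to current awakening). When a daily-distance table is
#' supplied its `dist_m` is merged in. Days without an active bin, and the
#' first tracked day of each fish (no previous rest onset), carry NA traits
#' with the corresponding valid flag FALSE.
#'
#' @param stateSequences a [StateSequence-class] or list of them (one per
#'   fish).
#' @param sunTable sun table covering all decoded dates.
#' @param tracks optional data.frame (fish_id, date, dist_m) of daily
#'   travelled distances, e.g. from [dailyDistance()].
#' @param minBout optional minimum active-bout length in bins (default 1 =
#'   off).
#' @return data.frame with columns fish_id, date, awakening_min, onset_min,
#'   rest_dur_h, dist_m and per-trait valid flags.
#' @export
buildTraitTable <- function(stateSequences, sunTable, tracks = NULL,
                            minBout = 1L) {
  if (is(stateSequences, "StateSequence"))
    stateSequences <- list(stateSequences)
  if (!length(stateSequences))
    return(data.frame(fish_id = character(), date = as.Date(character()),
                      awakening_min = numeric(), onset_min = numeric(),
                      rest_dur_h = numeric(), dist_m = numeric(),
                      valid_awakening = logical(), valid_onset = logical(),
                      valid_rest_dur = logical(), valid_dist = logical()))
  if (!is.null(tracks)) {
    seqIds <- sort(unique(vapply(stateSequences, function(s) s@fishId, "")))
    trkIds <- sort(unique(as.character(tracks$fish_id)))
    extra <- union(setdiff(seqIds, trkIds), setdiff(trkIds, seqIds))
    if (length(extra))
      stop("fish sets differ between states and tracks: ",
           paste(extra, collapse = ", "))
  }
  rows <- list()
  for (ss in stateSequences) {
    stopifnot(is(ss, "StateSequence"))
    state <- .filter_bouts(ss@state, minBout)
    df <- data.frame(bin_start = ss@binStart, state = state)
    attr(df, "binMinutes") <- ss@binMinutes
    dates <- .local_date(df$bin_start)
    udates <- sort(unique(dates))
    missing <- setdiff(format(udates), format(sunTable$date))
    if (length(missing))
      stop("sun table is missing date(s): ", paste(missing, collapse = ", "))
    prevOnsetAbs <- as.POSIXct(NA)
    for (d in seq_along(udates)) {
      day <- df[dates == udates[d], , drop = FALSE]
      attr(day, "binMinutes") <- ss@binMinutes
      srow <- match(udates[d], sunTable$date)
      aw <- awakeningTime(day, sunTable$sunrise[srow])
      on <- restOnset(day, sunTable$sunset[srow], ss@binMinutes)
      awAbs <- if (is.na(aw)) as.POSIXct(NA) else
        sunTable$sunrise[srow] + aw * 60
      dur <- if (d == 1L) NA_real_ else
        suppressWarnings(restDuration(prevOnsetAbs, awAbs))
      rows[[length(rows) + 1L]] <- data.frame(
        fish_id = ss@fishId, date = udates[d], awakening_min = aw,
        onset_min = on, rest_dur_h = dur, stringsAsFactors = FALSE)
      prevOnsetAbs <- if (is.na(on)) as.POSIXct(NA) else
        sunTable$sunset[srow] + on * 60
    }
  }
  out <- do.call(rbind, rows)
  out$dist_m <- NA_real_
  if (!is.null(tracks)) {
    key <- paste(out$fish_id, out$date)
    tkey <- paste(tracks$fish_id, as.Date(tracks$date))
    out$dist_m <- tracks$dist_m[match(key, tkey)]
  }
  out$valid_awakening <- !is.na(out$awakening_min)
  out$valid_onset <- !is.na(out$onset_min)
  out$valid_rest_dur <- !is.na(out$rest_dur_h)
  out$valid_dist <- !is.na(out$dist_m)
  rownames(out) <- NULL
  out
}

#' Summarize a daily trait table
#'
#' @param traitTable output of [buildTraitTable()].
#' @return data.frame of mean, sd and n of valid days per trait.
#' @export
traitSummary <- function(traitTable) {
  cols <- c(awakening_min = "awakening_min", onset_min = "onset_min",
            rest_dur_h = "rest_dur_h", dist_m = "dist_m")
  do.call(rbind, lapply(names(cols), function(nm) {
    v <- traitTable[[cols[[nm]]]]
    v <- v[!is.na(v)]
    data.frame(trait = nm, mean = mean(v), sd = sd(v), n = length(v))
  }))
}
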