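#' Construct an activity trace
#'
#' @param counts nonnegative integer minute-binned beam-crossing counts.
#' @param start_min minutes after midnight of day 1 at which the trace
#'   starts.
#' @param lights_on,lights_off clock times "HH:MM" defining the day phase
#'   `[lights_on, lights_off)`.
#' @param fly_id identifier.
#' @return object of class `activity_trace`.
#' @export
as_activity_trace <- function(counts, start_min = 0L,
                              lights_on = "08:00", lights_off = "20:00",
                              fly_id = 1L) {
  counts <- as.integer(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  structure(list(fly_id = fly_id, counts = counts,
                 start_min = as.integer(start_min),
                 lights_on_min = parse_clock(lights_on),
                 lights_off_min = parse_clock(lights_off)),
            class = "activity_trace")
}

#' Read a Trikinetics monitor file
#'
#' Expects tab-delimited rows: record index, date, time, a status field,
#' machine-status fields, then 32 channel counts. Rows whose status field
#' is not 1 are dropped with a message (their line numbers are recorded in
#' the `dropped_rows` attribute of each trace); any time gap between kept
#' rows not explained by a dropped row is an error.
#'
#' @param path monitor file.
#' @param lights_on,lights_off light schedule "HH:MM".
#' @return `activity_trace_set`: list of 32 `activity_trace` objects.
#' @export
read_dam <- function(path, lights_on = "08:00", lights_off = "20:00") {
  if (length(readLines(path, n = 1L)) == 0L) {
    return(structure(list(), class = "activity_trace_set"))
  }
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(raw) < 36L) {
    stop("malformed monitor file: expected >= 36 tab-delimited columns, got ",
         ncol(raw))
  }
  tm <- strsplit(raw[[3L]], ":", fixed = TRUE)
  bad_tm <- vapply(tm, length, 0L) < 2L
  if (any(bad_tm)) {
    stop("malformed time field at line ", which(bad_tm)[1L])
  }
  mins_of_day <- vapply(tm, function(p) {
    as.integer(p[1L]) * 60L + as.integer(p[2L])
  }, 0L)
  if (anyNA(mins_of_day)) {
    stop("malformed time field at line ", which(is.na(mins_of_day))[1L])
  }
  day_idx <- cumsum(c(0L, diff(mins_of_day) < 0L))  # midnight rollovers
  abs_min <- day_idx * 1440L + mins_of_day
  status <- raw[[4L]]
  keep <- status == 1L
  if (any(!keep)) {
    message("dropping ", sum(!keep), " row(s) with error status at line(s) ",
            paste(which(!keep), collapse = ", "))
  }
  gap <- diff(abs_min[keep])
  dropped_between <- vapply(seq_along(gap), function(i) {
    k <- which(keep)
    any(!keep[seq(k[i] + 1L, length.out = max(0L, k[i + 1L] - k[i] - 1L))])
  }, TRUE)
  if (any(gap != 1L & !dropped_between)) {
    stop("time gap > 1 minute at line ",
         which(keep)[which(gap != 1L & !dropped_between)[1L] + 1L])
  }
  cmat <- as.matrix(raw[keep, (ncol(raw) - 31L):ncol(raw)])
  if (!is.numeric(cmat) || any(is.na(cmat))) {
    stop("malformed count fields in monitor file")
  }
  traces <- lapply(1:32, function(ch) {
    tr <- as_activity_trace(cmat[, ch], start_min = abs_min[keep][1L],
                            lights_on = lights_on, lights_off = lights_off,
                            fly_id = ch)
    attr(tr, "dropped_rows") <- which(!keep)
    tr
  })
  structure(traces, class = "activity_trace_set")
}

#' Trim a trace to start at the first midnight
#'
#' Recordings include an acclimation period; analysis starts at the first
#' midnight at or after the start of the trace.
#'
#' @param trace an `activity_trace`.
#' @return the trimmed `activity_trace`.
#' @export
trim_to_midnight <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  rem <- trace$start_min %% 1440L
  if (rem == 0L) return(trace)
  drop <- 1440L - rem
  if (drop >= length(trace$counts)) stop("trace ends before first midnight")
  trace$counts <- trace$counts[-seq_len(drop)]
  trace$start_min <- trace$start_min + drop
  trace
}

minute_phase <- function(trace) {
  mod <- (trace$start_min + seq_along(trace$counts) - 1L) %% 1440L
  ifelse(mod >= trace$lights_on_min & mod < trace$lights_off_min,
         "day", "night")
}

#' Segment sleep bouts under the five-minute inactivity rule
#'
#' A sleep bout is a maximal run of consecutive zero-count minutes of
#' length at least five; shorter quiet runs are wake. Bouts spanning the
#' day/night boundary contribute their minutes to each phase separately
#' (`day_min`, `night_min`) but are counted once, attributed to the phase
#' holding the majority of the bout (ties go to the phase of the bout's
#' first minute). Bouts touching the trace start or end are kept and
#' flagged `edge`.
#'
#' @param trace an `activity_trace` (see [as_activity_trace()]).
#' @param min_duration minimum bout length in minutes (default 5).
#' @return data.frame with `start` (minute index within the trace),
#'   `duration`, `day_min`, `night_min`, `phase`, `edge`.
#' @export
detect_sleep_bouts <- function(trace, min_duration = 5L) {
  stopifnot(inherits(trace, "activity_trace"))
  if (length(trace$counts) < min_duration) {
    stop("trace must be at least ", min_duration, " minutes long")
  }
  r <- rle(trace$counts == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_duration
  if (!any(sel)) {
    return(data.frame(start = integer(0), duration = integer(0),
                      day_min = integer(0), night_min = integer(0),
                      phase = character(0), edge = logical(0)))
  }
  ph <- minute_phase(trace)
  out <- lapply(which(sel), function(i) {
    idx <- starts[i]:ends[i]
    dmin <- sum(ph[idx] == "day")
    nmin <- length(idx) - dmin
    phase <- if (dmin > nmin) "day" else if (nmin > dmin) "night"
             else ph[idx[1L]]
    data.frame(start = starts[i], duration = r$lengths[i],
               day_min = dmin, night_min = nmin, phase = phase,
               edge = starts[i] == 1L || ends[i] == length(trace$counts))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-fly sleep summary
#'
#' Day and night sleep proportions (sleep minutes over the phase's total
#' minutes in the trace), bout counts and mean bout lengths per phase
#' (bouts attributed to their majority phase), and the activity to
#' sleep-bout-length ratio, defined here as mean counts per waking minute
#' divided by mean sleep-bout length (the exact formula is recorded in
#' the `formula` attribute since upstream tools do not document theirs).
#'
#' @param trace an `activity_trace`.
#' @param bouts optional precomputed [detect_sleep_bouts()] output.
#' @param min_duration minimum bout length (minutes).
#' @return one-row data.frame: `fly_id`, `prop_sleep_day`,
#'   `prop_sleep_night`, `bout_count_day`, `bout_count_night`,
#'   `mean_bout_day`, `mean_bout_night`, `activity_to_sleep_bout_ratio`,
#'   `partial_phase` (TRUE when the trace covers less than one full day
#'   and one full night).
#' @export
summarize_sleep <- function(trace, bouts = NULL, min_duration = 5L) {
  stopifnot(inherits(trace, "activity_trace"))
  if (is.null(bouts)) bouts <- detect_sleep_bouts(trace, min_duration)
  ph <- minute_phase(trace)
  tot_day <- sum(ph == "day"); tot_night <- sum(ph == "night")
  day_sleep <- sum(bouts$day_min); night_sleep <- sum(bouts$night_min)
  day_bouts <- bouts[bouts$phase == "day", , drop = FALSE]
  night_bouts <- bouts[bouts$phase == "night", , drop = FALSE]
  sleep_min <- sum(bouts$duration)
  wake_idx <- rep(TRUE, length(trace$counts))
  for (i in seq_len(nrow(bouts))) {
    wake_idx[bouts$start[i]:(bouts$start[i] + bouts$duration[i] - 1L)] <- FALSE
  }
  mean_wake_activity <- if (any(wake_idx)) mean(trace$counts[wake_idx]) else NA_real_
  mean_bout_all <- if (nrow(bouts)) mean(bouts$duration) else NA_real_
  day_len <- trace$lights_off_min - trace$lights_on_min
  out <- data.frame(
    fly_id = trace$fly_id,
    prop_sleep_day = if (tot_day > 0) day_sleep / tot_day else NA_real_,
    prop_sleep_night = if (tot_night > 0) night_sleep / tot_night else NA_real_,
    bout_count_day = nrow(day_bouts),
    bout_count_night = nrow(night_bouts),
    mean_bout_day = if (nrow(day_bouts)) mean(day_bouts$duration) else NA_real_,
    mean_bout_night = if (nrow(night_bouts)) mean(night_bouts$duration) else NA_real_,
    activity_to_sleep_bout_ratio =
      if (!is.na(mean_bout_all)) mean_wake_activity / mean_bout_all else NA_real_,
    partial_phase = tot_day < day_len || tot_night < (1440L - day_len)
  )
  attr(out, "formula") <-
    "activity_to_sleep_bout_ratio = mean(counts | waking minute) / mean(bout duration)"
  out
}

#' Summaries for a whole trace set
#'
#' @param traces an `activity_trace_set`.
#' @param trim start each trace at its first midnight (acclimation
#'   exclusion) before summarizing.
#' @param ... passed to [summarize_sleep()].
#' @return data.frame, one row per fly.
#' @export
summarize_sleep_set <- function(traces, trim = TRUE, ...) {
  out <- lapply(traces, function(tr) {
    if (trim) tr <- trim_to_midnight(tr)
    summarize_sleep(tr, ...)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare sleep variables across genotypes and ages
#'
#' Applies the nonparametric cascade (Kruskal-Wallis then BH-adjusted
#' pairwise Wilcoxon rank-sum tests) to each sleep variable, separately
#' for each sex: genotypes are compared within each age, and ages within
#' each genotype.
#'
#' @param summaries data.frame of per-fly summaries with added `genotype`,
#'   `sex`, `age` columns.
#' @param variables summary columns to test.
#' @return nested list: `[[sex]][[variable]]$by_genotype[[age]]` and
#'   `[[sex]][[variable]]$by_age[[genotype]]`, each a
#'   [kw_pairwise_wilcoxon()] result (or `NULL` when fewer than two
#'   groups are present).
#' @export
compare_sleep_groups <- function(summaries,
                                 variables = c("prop_sleep_day",
                                               "prop_sleep_night",
                                               "bout_count_night",
                                               "mean_bout_night")) {
  stopifnot(all(c("genotype", "sex", "age") %in% names(summaries)),
            all(variables %in% names(summaries)))
  cascade <- function(v, g) {
    if (length(unique(g)) < 2L) return(NULL)
    kw_pairwise_wilcoxon(v, g)
  }
  lapply(split(summaries, summaries$sex), function(d) {
    res <- lapply(variables, function(var) {
      list(
        by_genotype = lapply(split(d, d$age), function(da) {
          cascade(da[[var]], da$genotype)
        }),
        by_age = lapply(split(d, d$genotype), function(dg) {
          cascade(dg[[var]], dg$age)
        })
      )
    })
    names(res) <- variables
    res
  })
}
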