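#' Parameters for the activity-monitor simulator
#'
#' Emulates minute-binned beam-crossing counts from a Drosophila Activity
#' Monitor. Each fly alternates between sleep and wake in a two-state
#' Markov chain at one-minute resolution with phase-dependent transition
#' probabilities, giving geometric bout lengths with means
#' `mean_bout_min_day` / `mean_bout_min_night` and stationary sleep
#' fractions `p_sleep_day` / `p_sleep_night`. Sleeping minutes emit zero
#' counts; waking minutes emit zero-truncated Poisson(`activity_rate`)
#' counts by default, so the five-minute inactivity rule is well posed
#' (an `untruncated` flag enables plain Poisson emissions to study
#' misclassification).
#'
#' @param n_flies flies per monitor (at most 32).
#' @param n_days recording days (default 3).
#' @param p_sleep_day,p_sleep_night stationary sleep probability per phase.
#' @param mean_bout_min_day,mean_bout_min_night mean sleep-bout length
#'   (minutes, >= 1) per phase.
#' @param activity_rate mean counts per waking minute.
#' @param lights_on,lights_off clock times "HH:MM" (12:12 LD default).
#' @param untruncated if `TRUE`, waking minutes emit untruncated Poisson
#'   counts (so silent wake minutes can masquerade as sleep).
#' @param seed integer RNG seed.
#' @return object of class `dam_sim_params`.
#' @export
dam_sim_params <- function(n_flies = 32, n_days = 3, p_sleep_day = 0.4,
                           p_sleep_night = 0.7, mean_bout_min_day = 20,
                           mean_bout_min_night = 40, activity_rate = 2,
                           lights_on = "08:00", lights_off = "20:00",
                           untruncated = FALSE, seed = 1) {
  check_prob(p_sleep_day, "p_sleep_day")
  check_prob(p_sleep_night, "p_sleep_night")
  stopifnot(n_flies >= 1, n_flies <= 32, n_days >= 1,
            mean_bout_min_day >= 1, mean_bout_min_night >= 1,
            activity_rate >= 0)
  structure(list(n_flies = n_flies, n_days = n_days,
                 p_sleep_day = p_sleep_day, p_sleep_night = p_sleep_night,
                 mean_bout_min_day = mean_bout_min_day,
                 mean_bout_min_night = mean_bout_min_night,
                 activity_rate = activity_rate,
                 lights_on = lights_on, lights_off = lights_off,
                 untruncated = isTRUE(untruncated), seed = seed),
            class = "dam_sim_params")
}

parse_clock <- function(x) {
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  if (length(p) < 2L || anyNA(p[1:2])) stop("clock time must be HH:MM")
  p[1L] * 60L + p[2L]
}

# Markov transition probabilities reproducing (stationary fraction, mean
# sleep-bout length) for one phase; degenerate fractions handled exactly.
phase_rates <- function(p_sleep, mean_bout) {
  if (p_sleep >= 1) return(c(s2w = 0, w2s = 1))
  if (p_sleep <= 0) return(c(s2w = 1, w2s = 0))
  s2w <- 1 / mean_bout
  w2s <- min(1, p_sleep * s2w / (1 - p_sleep))
  c(s2w = s2w, w2s = w2s)
}

#' Simulate activity-monitor traces
#'
#' @param params a [dam_sim_params()] object.
#' @return object of class `activity_trace_set`: a list of
#'   `activity_trace` objects (fields `fly_id`, `counts`, `start_min`
#'   minutes after midnight of day 1, `lights_on_min`, `lights_off_min`),
#'   plus the ground-truth sleep state matrix in attribute `truth`.
#' @export
gen_dam <- function(params) {
  stopifnot(inherits(params, "dam_sim_params"))
  if (params$activity_rate == 0 && !params$untruncated) {
    warning("activity_rate = 0: every minute is silent and will be ",
            "classified as sleep downstream")
  }
  on_min <- parse_clock(params$lights_on)
  off_min <- parse_clock(params$lights_off)
  n_min <- params$n_days * 1440L
  minute_of_day <- (seq_len(n_min) - 1L) %% 1440L
  is_day <- minute_of_day >= on_min & minute_of_day < off_min
  rd <- phase_rates(params$p_sleep_day, params$mean_bout_min_day)
  rn <- phase_rates(params$p_sleep_night, params$mean_bout_min_night)
  nf <- params$n_flies
  with_seed(stream_seed(params$seed, "dam"), {
    # state TRUE = asleep; recording starts at midnight (night phase)
    asleep <- matrix(FALSE, nrow = n_min, ncol = nf)
    p0 <- if (is_day[1L]) params$p_sleep_day else params$p_sleep_night
    state <- stats::runif(nf) < p0
    asleep[1L, ] <- state
    for (m in 2L:n_min) {
      r <- if (is_day[m]) rd else rn
      u <- stats::runif(nf)
      state <- ifelse(state, u >= r[["s2w"]], u < r[["w2s"]])
      asleep[m, ] <- state
    }
    counts <- matrix(0L, nrow = n_min, ncol = nf)
    wake_idx <- which(!asleep)
    if (length(wake_idx) && params$activity_rate > 0) {
      counts[wake_idx] <- as.integer(if (params$untruncated) {
        stats::rpois(length(wake_idx), params$activity_rate)
      } else {
        rztpois(length(wake_idx), params$activity_rate)
      })
    }
    traces <- lapply(seq_len(nf), function(f) {
      structure(list(fly_id = f, counts = counts[, f], start_min = 0L,
                     lights_on_min = on_min, lights_off_min = off_min),
                class = "activity_trace")
    })
    structure(traces, class = "activity_trace_set", truth = asleep,
              params = params)
  })
}

#' Write traces as a Trikinetics-style monitor file
#'
#' Tab-delimited, one row per minute: record index, date, time, a status
#' field (1 = valid), six machine-status fields, then 32 channel counts
#' (unused channels zero-filled).
#'
#' @param traces an `activity_trace_set` (all traces equal length).
#' @param path output file.
#' @param start_date date of the first row (the recording starts at
#'   midnight).
#' @return `path`, invisibly.
#' @export
write_dam <- function(traces, path, start_date = as.Date("2026-01-05")) {
  stopifnot(length(traces) >= 1L, length(traces) <= 32L)
  n_min <- unique(vapply(traces, function(t) length(t$counts), 0L))
  if (length(n_min) != 1L) stop("traces must have equal length")
  cmat <- matrix(0L, nrow = n_min, ncol = 32L)
  for (i in seq_along(traces)) cmat[, i] <- traces[[i]]$counts
  mins <- seq_len(n_min) - 1L
  dates <- format(start_date + mins %/% 1440L, "%d %b %y")
  times <- sprintf("%02d:%02d:00", (mins %% 1440L) %/% 60L, mins %% 60L)
  meta <- cbind(seq_len(n_min), dates, times, 1L,
                matrix(0L, nrow = n_min, ncol = 6L))
  utils::write.table(cbind(meta, cmat), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
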