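#' Parameters for the lifespan simulator
#'
#' Death times are drawn per group from a Weibull or Gompertz
#' distribution, rounded UP to the census grid (deaths are discovered at
#' the next every-other-day count), and right-censored at the study
#' horizon.
#'
#' @param groups named list; each element is a list with `dist`
#'   ("weibull" or "gompertz") and its parameters (`shape`/`scale` for
#'   Weibull, `rate`/`shape` for Gompertz as in [flexsurv::rgompertz()]).
#' @param n_per_group flies per group.
#' @param census_interval_days counting interval (default 2).
#' @param max_day study horizon (default 100).
#' @param seed integer RNG seed.
#' @return object of class `survival_sim_params`.
#' @export
survival_sim_params <- function(groups = list(
                                  control = list(dist = "weibull",
                                                 shape = 4, scale = 90)),
                                n_per_group = 150,
                                census_interval_days = 2, max_day = 100,
                                seed = 1) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            n_per_group >= 1, census_interval_days >= 1, max_day > 0)
  for (g in groups) {
    if (!g$dist %in% c("weibull", "gompertz")) {
      stop("dist must be 'weibull' or 'gompertz'")
    }
  }
  structure(list(groups = groups, n_per_group = n_per_group,
                 census_interval_days = census_interval_days,
                 max_day = max_day, seed = seed),
            class = "survival_sim_params")
}

#' Simulate per-fly survival records
#'
#' @param params a [survival_sim_params()] object.
#' @return data.frame with `fly_id`, `group`, `time_days` (on the census
#'   grid), `event` (1 = died, 0 = censored at the horizon) and the true
#'   (continuous) death time in `true_time`.
#' @export
gen_survival <- function(params) {
  stopifnot(inherits(params, "survival_sim_params"))
  with_seed(stream_seed(params$seed, "survival"), {
    out <- lapply(names(params$groups), function(gname) {
      g <- params$groups[[gname]]
      t <- if (g$dist == "weibull") {
        stats::rweibull(params$n_per_group, shape = g$shape,
                        scale = g$scale)
      } else {
        flexsurv::rgompertz(params$n_per_group, shape = g$shape,
                            rate = g$rate)
      }
      grid <- ceiling(t / params$census_interval_days) *
        params$census_interval_days
      event <- as.integer(grid <= params$max_day)
      data.frame(group = gname,
                 time_days = ifelse(event == 1L, grid, params$max_day),
                 event = event, true_time = t,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out <- cbind(fly_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}
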