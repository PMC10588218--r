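#' Parameters for the Y-maze arm-entry simulator
#'
#' The generator emulates the spontaneous-alternation assay: each fly runs
#' `n_trials` one-minute trials, producing an ordered sequence of arm
#' entries per trial plus a distance moved. Entries follow a second-order
#' Markov process on the three arms: with probability `p_reentry` the fly
#' re-enters its current arm; otherwise it chooses between the two other
#' arms such that the alternation-completing arm (the arm different from
#' the one visited two entries back) is taken with probability
#' `p_alternate`. `p_alternate = 0.5`, `p_reentry = 0` is the unbiased
#' null under which the expected alternation score is exactly 0.5 and each
#' arm is entered 1/3 of the time.
#'
#' @param n_flies number of flies.
#' @param entries_per_trial mean entries per trial (Poisson).
#' @param n_trials trials per fly (default 10).
#' @param p_alternate probability the non-reentry choice completes an
#'   alternation.
#' @param p_reentry probability of re-entering the current arm.
#' @param distance_rate mean distance moved per entry (mm).
#' @param seed integer RNG seed.
#' @return object of class `ymaze_sim_params`.
#' @export
ymaze_sim_params <- function(n_flies = 30, entries_per_trial = 8,
                             n_trials = 10, p_alternate = 0.5,
                             p_reentry = 0.1, distance_rate = 12,
                             seed = 1) {
  check_prob(p_alternate, "p_alternate")
  check_prob(p_reentry, "p_reentry")
  stopifnot(n_flies >= 1, n_trials >= 1, entries_per_trial > 0,
            distance_rate > 0)
  structure(list(n_flies = n_flies, entries_per_trial = entries_per_trial,
                 n_trials = n_trials, p_alternate = p_alternate,
                 p_reentry = p_reentry, distance_rate = distance_rate,
                 seed = seed),
            class = "ymaze_sim_params")
}

ARMS <- c("A", "B", "C")

sim_entry_chain <- function(n, p_alternate, p_reentry) {
  if (n == 0L) return(character(0))
  e <- character(n)
  e[1L] <- sample(ARMS, 1L)
  if (n >= 2L) {
    e[2L] <- if (stats::runif(1) < p_reentry) e[1L] else
      sample(setdiff(ARMS, e[1L]), 1L)
  }
  if (n >= 3L) {
    for (k in 3L:n) {
      prev1 <- e[k - 1L]; prev2 <- e[k - 2L]
      if (stats::runif(1) < p_reentry) {
        e[k] <- prev1
      } else {
        others <- setdiff(ARMS, prev1)
        if (prev2 == prev1) {
          e[k] <- sample(others, 1L)
        } else {
          third <- setdiff(others, prev2)  # completes the alternation
          e[k] <- if (stats::runif(1) < p_alternate) third else prev2
        }
      }
    }
  }
  e
}

#' Simulate Y-maze arm-entry sequences
#'
#' @param params a [ymaze_sim_params()] object.
#' @param trajectories if `TRUE`, also render a 2-D center-to-arm-tip
#'   trajectory for every entry (for testing entry detection).
#' @param geometry maze geometry used for trajectory rendering, see
#'   [ymaze_geometry()].
#' @return list with `entries` (data.frame fly_id, trial, entry_index,
#'   arm), `distance` (data.frame fly_id, trial, distance_mm), optionally
#'   `trajectory` (data.frame fly_id, trial, t, x, y), and `params`.
#' @export
gen_ymaze <- function(params, trajectories = FALSE,
                      geometry = ymaze_geometry()) {
  stopifnot(inherits(params, "ymaze_sim_params"))
  with_seed(stream_seed(params$seed, "ymaze"), {
    ent <- list(); dst <- list(); trj <- list()
    for (f in seq_len(params$n_flies)) {
      for (tr in seq_len(params$n_trials)) {
        n <- stats::rpois(1L, params$entries_per_trial)
        arms <- sim_entry_chain(n, params$p_alternate, params$p_reentry)
        d <- if (n > 0L) {
          stats::rgamma(1L, shape = n, rate = 1 / params$distance_rate)
        } else 0
        ent[[length(ent) + 1L]] <- if (n > 0L) {
          data.frame(fly_id = f, trial = tr, entry_index = seq_len(n),
                     arm = arms, stringsAsFactors = FALSE)
        } else NULL
        dst[[length(dst) + 1L]] <-
          data.frame(fly_id = f, trial = tr, distance_mm = d)
        if (trajectories && n > 0L) {
          trj[[length(trj) + 1L]] <-
            render_trajectory(arms, geometry, fly_id = f, trial = tr)
        }
      }
    }
    out <- list(
      entries = do.call(rbind, ent) %||%
        data.frame(fly_id = integer(0), trial = integer(0),
                   entry_index = integer(0), arm = character(0)),
      distance = do.call(rbind, dst),
      params = params
    )
    if (trajectories) out$trajectory <- do.call(rbind, trj)
    out
  })
}

# Piecewise-linear path: center -> 80% of arm length -> center, per entry.
render_trajectory <- function(arms, geometry, fly_id = 1L, trial = 1L,
                              pts_per_leg = 8L) {
  segs <- lapply(seq_along(arms), function(i) {
    ax <- geometry$arm_axes[[arms[i]]]
    depth <- seq(0, 0.8 * geometry$arm_length, length.out = pts_per_leg)
    d <- c(depth, rev(depth)[-1L])
    r <- geometry$center_radius * 0.3 + d
    data.frame(x = r * ax[1L], y = r * ax[2L])
  })
  path <- do.call(rbind, segs)
  data.frame(fly_id = fly_id, trial = trial, t = seq_len(nrow(path)),
             x = path$x, y = path$y)
}
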