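#' Y-maze geometry
#'
#' Builds the zone polygons used for arm-entry detection: a central zone
#' (regular 24-gon approximating a disc of radius `center_radius`) and
#' three rectangular arms of length `arm_length` and width `arm_width`
#' radiating at 90, 210 and 330 degrees. Units are arbitrary but must
#' match the trajectory coordinates (mm in practice).
#'
#' @param arm_length,arm_width,center_radius maze dimensions.
#' @return object of class `ymaze_geometry`: list with `center` (polygon
#'   matrix), `arms` (named list of polygon matrices), `arm_axes` (unit
#'   vectors), `arm_length`, `center_radius`.
#' @export
ymaze_geometry <- function(arm_length = 15, arm_width = 3,
                           center_radius = 3) {
  stopifnot(arm_length > 0, arm_width > 0, center_radius > 0)
  ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
  center <- cbind(center_radius * cos(ang), center_radius * sin(ang))
  axes <- list(A = c(0, 1),
               B = c(cos(210 * pi / 180), sin(210 * pi / 180)),
               C = c(cos(330 * pi / 180), sin(330 * pi / 180)))
  arms <- lapply(axes, function(ax) {
    perp <- c(-ax[2L], ax[1L]) * arm_width / 2
    p1 <- ax * center_radius
    p2 <- ax * (center_radius + arm_length)
    rbind(p1 + perp, p2 + perp, p2 - perp, p1 - perp)
  })
  structure(list(center = center, arms = arms, arm_axes = axes,
                 arm_length = arm_length, center_radius = center_radius),
            class = "ymaze_geometry")
}

check_geometry <- function(geometry) {
  if (!inherits(geometry, "ymaze_geometry")) {
    ok <- is.list(geometry) && all(c("center", "arms", "arm_axes",
                                     "arm_length") %in% names(geometry))
    if (!ok) stop("malformed maze geometry")
  }
  polys <- c(list(geometry$center), geometry$arms)
  for (p in polys) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L ||
        anyNA(p) || !is.numeric(p)) {
      stop("malformed maze geometry: zone polygons must be numeric ",
           "n x 2 matrices with n >= 3")
    }
  }
  invisible(geometry)
}

#' Detect arm entries from a 2-D trajectory
#'
#' An entry is recorded when the animal passes from the central zone into
#' an arm and penetrates beyond a debounce depth (a fraction of the arm
#' length, guarding against boundary jitter). Consecutive samples inside
#' the same arm yield a single entry; returning to the center and
#' re-entering (any arm, including the same one) yields a new entry.
#'
#' @param traj data.frame with columns `x`, `y` (and optionally `t`),
#'   ordered in time.
#' @param geometry a [ymaze_geometry()] object.
#' @param debounce_frac penetration depth required to commit an entry, as
#'   a fraction of arm length (default 0.1).
#' @return data.frame with `entry_index`, `arm`, and the row index of the
#'   committing sample (`sample`). A trajectory that never commits to an
#'   arm returns zero rows.
#' @export
detect_arm_entries <- function(traj, geometry = ymaze_geometry(),
                               debounce_frac = 0.1) {
  check_geometry(geometry)
  stopifnot(is.data.frame(traj), all(c("x", "y") %in% names(traj)))
  xy <- cbind(traj$x, traj$y)
  n <- nrow(xy)
  if (n == 0L) {
    return(data.frame(entry_index = integer(0), arm = character(0),
                      sample = integer(0)))
  }
  in_center <- mgcv::in.out(rbind(geometry$center, geometry$center[1L, ]),
                            xy)
  arm_names <- names(geometry$arms)
  in_arm <- sapply(arm_names, function(a) {
    mgcv::in.out(rbind(geometry$arms[[a]], geometry$arms[[a]][1L, ]), xy)
  })
  if (is.null(dim(in_arm))) in_arm <- matrix(in_arm, nrow = 1L)
  # depth of penetration along each arm axis, past the central zone
  depth <- sapply(arm_names, function(a) {
    ax <- geometry$arm_axes[[a]]
    xy[, 1L] * ax[1L] + xy[, 2L] * ax[2L] - geometry$center_radius
  })
  if (is.null(dim(depth))) depth <- matrix(depth, nrow = 1L)
  need <- debounce_frac * geometry$arm_length
  committed <- "center"
  entries <- character(0); at <- integer(0)
  for (i in seq_len(n)) {
    if (in_center[i]) {
      committed <- "center"
    } else {
      hit <- which(in_arm[i, ])
      if (length(hit) == 1L) {
        a <- arm_names[hit]
        if (depth[i, hit] >= need && committed != a) {
          entries <- c(entries, a)
          at <- c(at, i)
          committed <- a
        }
      }
    }
  }
  data.frame(entry_index = seq_along(entries), arm = entries, sample = at,
             stringsAsFactors = FALSE)
}

# n_alt / attempts for one ordered arm sequence
alternation_counts <- function(arms, window = c("sliding", "disjoint")) {
  window <- match.arg(window)
  n <- length(arms)
  starts <- if (window == "sliding") {
    if (n >= 3L) seq_len(n - 2L) else integer(0)
  } else {
    if (n >= 3L) seq(1L, n - 2L, by = 3L) else integer(0)
  }
  n_alt <- 0L
  for (s in starts) {
    w <- arms[s:(s + 2L)]
    if (length(unique(w)) == 3L) n_alt <- n_alt + 1L
  }
  c(n_alt = n_alt, a_max = length(starts))
}

#' Score spontaneous alternation
#'
#' Within each trial, every window of three consecutive arm entries is an
#' alternation attempt; an attempt counts as an alternation when its three
#' entries are pairwise distinct. Alternations and attempts are summed
#' within each trial, the per-trial ratio formed, and the fly's score is
#' the mean ratio over trials with at least one attempt (`mode =
#' "per_trial"`, the default aggregation) or the pooled ratio
#' sum(alternations)/sum(attempts) (`mode = "pooled"`). Flies with no
#' attempts in any trial carry an `NA` score and are flagged.
#'
#' @param entries data.frame with columns `fly_id`, `trial`, `arm` (as
#'   produced by [gen_ymaze()]), or a character vector of arms treated as
#'   one fly, one trial.
#' @param mode per-trial ratio averaging (default) or pooled ratio.
#' @param window `"sliding"` (overlapping windows, default) or
#'   `"disjoint"` (non-overlapping triplets).
#' @return data.frame with one row per fly: `fly_id`, `n_alt`, `a_max`
#'   (totals across trials), `score`, `n_trials_scored`, `no_score`.
#' @export
score_alternations <- function(entries, mode = c("per_trial", "pooled"),
                               window = c("sliding", "disjoint")) {
  mode <- match.arg(mode); window <- match.arg(window)
  if (is.character(entries)) {
    entries <- data.frame(fly_id = 1L, trial = 1L, arm = entries,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("fly_id", "trial", "arm") %in% names(entries)))
  if (nrow(entries) > 0 && !all(entries$arm %in% ARMS)) {
    stop("arm labels must be drawn from {A, B, C}")
  }
  out <- lapply(split(entries, entries$fly_id), function(ef) {
    per_trial <- lapply(split(ef$arm, ef$trial), alternation_counts,
                        window = window)
    na <- vapply(per_trial, `[`, 0L, "n_alt")
    am <- vapply(per_trial, `[`, 0L, "a_max")
    scored <- am > 0L
    score <- if (!any(scored)) {
      NA_real_
    } else if (mode == "per_trial") {
      mean(na[scored] / am[scored])
    } else {
      sum(na) / sum(am)
    }
    data.frame(fly_id = ef$fly_id[1L], n_alt = sum(na), a_max = sum(am),
               score = score, n_trials_scored = sum(scored),
               no_score = !any(scored))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-fly arm-entry bias with cohort signed-rank tests
#'
#' Computes each fly's fraction of entries into arms A, B and C (pooled
#' over trials) and tests each arm's cohort fractions against the uniform
#' null of 1/3 with a two-sided Wilcoxon signed-rank test. Flies with
#' zero entries are excluded with a message.
#'
#' @param entries data.frame with `fly_id`, `arm` columns.
#' @return list with `per_fly` (data.frame fly_id, A, B, C) and `tests`
#'   (data.frame arm, statistic, p_value, n_used).
#' @export
arm_bias <- function(entries) {
  stopifnot(all(c("fly_id", "arm") %in% names(entries)))
  fid <- if (is.factor(entries$fly_id)) entries$fly_id
         else factor(entries$fly_id)
  counts <- table(fid, factor(entries$arm, levels = ARMS))
  tot <- rowSums(counts)
  if (any(tot == 0L)) {
    message("excluding ", sum(tot == 0L), " fly/flies with zero entries")
  }
  keep <- tot > 0L
  frac <- sweep(counts[keep, , drop = FALSE], 1L, tot[keep], "/")
  per_fly <- data.frame(fly_id = rownames(frac),
                        A = frac[, "A"], B = frac[, "B"], C = frac[, "C"],
                        row.names = NULL, stringsAsFactors = FALSE)
  tests <- do.call(rbind, lapply(ARMS, function(a) {
    tr <- signed_rank_test(frac[, a], null_value = 1 / 3)
    cbind(arm = a, tr)
  }))
  list(per_fly = per_fly, tests = tests)
}

#' Distance-scaled alternation
#'
#' Total alternations divided by total distance moved (alternations per
#' mm), the movement-corrected working-memory metric.
#'
#' @param n_alt total alternations (per fly).
#' @param distance_mm total distance moved (per fly, mm).
#' @return numeric vector of alternations per mm; `NA` (with a warning)
#'   where distance is zero.
#' @export
distance_scaled_alternation <- function(n_alt, distance_mm) {
  stopifnot(length(n_alt) == length(distance_mm), all(distance_mm >= 0))
  out <- ifelse(distance_mm > 0, n_alt / distance_mm, NA_real_)
  if (anyNA(out)) warning("zero-distance fly/flies: metric undefined (NA)")
  out
}

#' Compare a Y-maze metric across genotypes
#'
#' Runs the study's dual testing convention separately per sex: with
#' pooled replicates (more than one replicate label), a fixed-effects
#' linear model with replicate as a fixed effect, ANOVA, and Tukey HSD;
#' with a single replicate, the nonparametric cascade (Kruskal-Wallis
#' followed by BH-adjusted pairwise Wilcoxon rank-sum tests).
#'
#' @param data data.frame with the metric column, `genotype`, `sex`, and
#'   optionally `replicate`.
#' @param metric name of the metric column (e.g. "score").
#' @param path "auto" (default: parametric iff >1 replicate),
#'   "parametric", or "nonparametric".
#' @return named list (one element per sex) of [anova_tukey()] or
#'   [kw_pairwise_wilcoxon()] results, each tagged with `$path`.
#' @export
compare_ymaze_groups <- function(data, metric = "score",
                                 path = c("auto", "parametric",
                                          "nonparametric")) {
  path <- match.arg(path)
  stopifnot(metric %in% names(data), "genotype" %in% names(data))
  if (!"sex" %in% names(data)) data$sex <- "pooled"
  if (length(unique(data$genotype)) < 2L) stop("missing group: need >= 2 genotypes")
  lapply(split(data, data$sex), function(d) {
    d <- d[!is.na(d[[metric]]), ]
    n_rep <- if ("replicate" %in% names(d)) {
      length(unique(d$replicate))
    } else 1L
    use_param <- switch(path, auto = n_rep > 1L,
                        parametric = TRUE, nonparametric = FALSE)
    res <- if (use_param) {
      anova_tukey(d[[metric]], d$genotype,
                  block = if (n_rep > 1L) d$replicate else NULL)
    } else {
      kw_pairwise_wilcoxon(d[[metric]], d$genotype)
    }
    res$path <- if (use_param) "parametric" else "nonparametric"
    res
  })
}
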