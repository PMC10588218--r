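# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Benjamini-Hochberg step-up: adj_i = min_{k: p_k >= p_i-rank} (p_k * n / rank_k)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Sliding-window alternation scoring by direct enumeration.
oracle_alternation <- function(arms) {
  n_alt <- 0L; a_max <- 0L
  if (length(arms) >= 3L) {
    for (s in 1:(length(arms) - 2L)) {
      a_max <- a_max + 1L
      if (length(unique(arms[s:(s + 2L)])) == 3L) n_alt <- n_alt + 1L
    }
  }
  c(n_alt = n_alt, a_max = a_max)
}

# All 3^n arm sequences of length n as a character matrix.
all_arm_sequences <- function(n) {
  g <- do.call(expand.grid, rep(list(c("A", "B", "C")), n))
  as.matrix(g)[, rev(seq_len(n)), drop = FALSE]
}

# Minute-by-minute sleep-bout scan (five-minute rule).
oracle_sleep_bouts <- function(counts, min_dur = 5L) {
  bouts <- NULL
  run <- 0L
  for (i in seq_along(counts)) {
    if (counts[i] == 0L) {
      run <- run + 1L
    } else {
      if (run >= min_dur) bouts <- rbind(bouts, c(i - run, run))
      run <- 0L
    }
  }
  if (run >= min_dur) {
    bouts <- rbind(bouts, c(length(counts) + 1L - run, run))
  }
  if (is.null(bouts)) {
    return(data.frame(start = integer(0), duration = integer(0)))
  }
  data.frame(start = bouts[, 1L], duration = bouts[, 2L])
}

# Product-limit estimator straight from the definition, deaths before
# censorings at ties.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time > tt[i] | (time == tt[i]))  # censored at t still at risk
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# Per-pixel Bernsen evaluation with an explicit window loop.
oracle_bernsen <- function(img, radius, contrast_threshold,
                           bright_background = FALSE) {
  ny <- nrow(img); nx <- ncol(img)
  gm <- (max(img) + min(img)) / 2
  out <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      vals <- c()
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          if (di * di + dj * dj <= radius * radius) {
            y <- i + di; x <- j + dj
            if (y >= 1 && y <= ny && x >= 1 && x <= nx) {
              vals <- c(vals, img[y, x])
            }
          }
        }
      }
      mid <- (max(vals) + min(vals)) / 2
      if (max(vals) - min(vals) < contrast_threshold) {
        out[i, j] <- if (bright_background) mid < gm else mid >= gm
      } else {
        out[i, j] <- img[i, j] >= mid
      }
    }
  }
  out
}
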