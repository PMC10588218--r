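test_that("alternation scoring matches hand-derived examples", {
  expect_equal(score_alternations(c("A", "B", "C", "A", "B", "C"))$score, 1)
  expect_equal(score_alternations(c("A", "B", "A", "B"))$score, 0)
  r <- score_alternations(c("A", "B", "C", "B"))
  expect_equal(r$n_alt, 1L)
  expect_equal(r$a_max, 2L)
  expect_equal(r$score, 0.5)
  # disjoint-window mode: ABCABC has two non-overlapping triplets
  rd <- score_alternations(c("A", "B", "C", "A", "B", "C"),
                           window = "disjoint")
  expect_equal(rd$a_max, 2L)
  expect_equal(rd$score, 1)
  expect_error(score_alternations(c("A", "B", "D")), "\\{A, B, C\\}")
})

test_that("alternation scoring equals brute-force enumeration (n <= 6)", {
  for (n in c(3L, 4L, 6L)) {
    seqs <- all_arm_sequences(n)
    for (i in seq_len(nrow(seqs))) {
      arms <- unname(seqs[i, ])
      got <- score_alternations(arms)
      want <- oracle_alternation(arms)
      expect_identical(c(got$n_alt, got$a_max),
                       c(want[["n_alt"]], want[["a_max"]]))
    }
  }
})

test_that("per-trial aggregation averages trial ratios; pooled mode pools", {
  ent <- data.frame(fly_id = 1L,
                    trial = c(1, 1, 1, 2, 2, 2, 2),
                    arm = c("A", "B", "C", "A", "B", "A", "B"))
  per <- score_alternations(ent, mode = "per_trial")
  expect_equal(per$score, mean(c(1, 0)))
  pool <- score_alternations(ent, mode = "pooled")
  expect_equal(pool$score, 1 / 3)
  # a fly with < 3 entries in every trial has no score and is flagged
  short <- data.frame(fly_id = 2L, trial = c(1, 1, 2), arm = c("A", "B", "C"))
  r <- score_alternations(short)
  expect_true(r$no_score)
  expect_true(is.na(r$score))
})

test_that("dropping a trial never increases total alternations", {
  set.seed(17)
  for (i in 1:25) {
    sim <- gen_ymaze(ymaze_sim_params(n_flies = 1, n_trials = 4,
                                      seed = 1000 + i))
    full <- score_alternations(sim$entries)
    drop1 <- score_alternations(sim$entries[sim$entries$trial != 2, ])
    expect_lte(drop1$n_alt, full$n_alt)
    sc <- full$score
    if (!is.na(sc)) expect_true(sc >= 0 && sc <= 1)
  }
})

test_that("arm entries are detected from trajectories with debounce", {
  geo <- ymaze_geometry()
  leg <- function(arm, depth) {
    ax <- geo$arm_axes[[arm]]
    r <- c(seq(1, geo$center_radius + depth, length.out = 12),
           seq(geo$center_radius + depth, 1, length.out = 12))
    data.frame(x = r * ax[1], y = r * ax[2])
  }
  path <- rbind(leg("A", 10), leg("B", 10), leg("C", 10))
  expect_equal(detect_arm_entries(path, geo)$arm, c("A", "B", "C"))

  # same-arm re-entry through the center is a new entry
  path2 <- rbind(leg("A", 10), leg("A", 10))
  expect_equal(detect_arm_entries(path2, geo)$arm, c("A", "A"))

  # dithering on the arm mouth below the debounce depth: one entry only
  dither <- do.call(rbind, replicate(6, leg("A", 0.8), simplify = FALSE))
  deep_then_dither <- rbind(leg("A", 10), dither)
  expect_equal(detect_arm_entries(deep_then_dither, geo)$arm, "A")
  # dithering alone never commits
  expect_equal(nrow(detect_arm_entries(dither, geo)), 0L)

  expect_equal(nrow(detect_arm_entries(data.frame(x = numeric(0),
                                                  y = numeric(0)), geo)), 0L)
  bad <- ymaze_geometry()
  bad$arms$A <- matrix(1, 2, 2)
  expect_error(detect_arm_entries(path, bad), "malformed")
})

test_that("detection reproduces the generator's entry sequences", {
  sim <- gen_ymaze(ymaze_sim_params(n_flies = 3, n_trials = 2, seed = 12),
                   trajectories = TRUE)
  for (f in 1:3) {
    for (tr in 1:2) {
      tj <- sim$trajectory[sim$trajectory$fly_id == f &
                             sim$trajectory$trial == tr, ]
      truth <- sim$entries$arm[sim$entries$fly_id == f &
                                 sim$entries$trial == tr]
      if (nrow(tj) == 0) next
      expect_equal(detect_arm_entries(tj)$arm, truth)
    }
  }
})

test_that("arm bias fractions and cohort tests behave", {
  ent <- data.frame(fly_id = 1L, arm = c("A", "A", "A", "B"))
  ab <- arm_bias(ent)
  expect_equal(unlist(ab$per_fly[1, c("A", "B", "C")], use.names = FALSE),
               c(0.75, 0.25, 0))

  # planted bias toward A at n = 30: signed-rank detects it
  set.seed(23)
  biased <- do.call(rbind, lapply(1:30, function(f) {
    data.frame(fly_id = f,
               arm = sample(c("A", "B", "C"), 40, replace = TRUE,
                            prob = c(0.45, 0.275, 0.275)))
  }))
  tb <- arm_bias(biased)$tests
  expect_lt(tb$p_value[tb$arm == "A"], 0.05)

  # zero-entry fly excluded with a message
  ent0 <- rbind(ent, data.frame(fly_id = 2L, arm = "A")[0, ])
  ent0$fly_id <- factor(ent0$fly_id, levels = c(1, 2))
  expect_message(arm_bias(ent0), "zero entries")
})

test_that("distance scaling is a pure ratio", {
  expect_equal(distance_scaled_alternation(10, 500), 0.02)
  expect_equal(distance_scaled_alternation(10, 1000),
               distance_scaled_alternation(10, 500) / 2)
  expect_warning(out <- distance_scaled_alternation(c(3, 4), c(100, 0)),
                 "zero-distance")
  expect_true(is.na(out[2]))
})

test_that("group comparison runs both testing paths, sexes separately", {
  set.seed(29)
  df <- expand.grid(fly = 1:25, genotype = c("ctl", "oe"),
                    sex = c("m", "f"), replicate = c("r1", "r2"))
  df$score <- rnorm(nrow(df), 0.6, 0.05) - (df$genotype == "oe") * 0.06
  res <- compare_ymaze_groups(df, metric = "score")
  expect_setequal(names(res), c("f", "m"))
  expect_equal(res$m$path, "parametric")
  expect_lt(res$m$anova$p_value[res$m$anova$term == "group"], 0.01)

  single <- df[df$replicate == "r1", ]
  single$replicate <- NULL
  res_np <- compare_ymaze_groups(single, metric = "score")
  expect_equal(res_np$m$path, "nonparametric")
  expect_error(compare_ymaze_groups(df[df$genotype == "ctl", ], "score"),
               "missing group")
})
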