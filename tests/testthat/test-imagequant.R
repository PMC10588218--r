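disc_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx),
        function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("nuclear/whole-cell ratio is exact on constructed cells", {
  img <- array(0.5, c(16, 16, 2))
  nuc <- array(FALSE, dim(img)); nuc[6:10, 6:10, ] <- TRUE
  cell <- array(FALSE, dim(img)); cell[3:13, 3:13, ] <- TRUE
  expect_equal(nuclear_total_ratio(img, nuc, cell)$ratio, 1)

  img0 <- img; img0[nuc] <- 0
  expect_equal(nuclear_total_ratio(img0, nuc, cell)$ratio, 0)

  # invariant to global intensity scaling
  set.seed(3)
  imgr <- array(runif(512), dim(img))
  r1 <- nuclear_total_ratio(imgr, nuc, cell)$ratio
  r2 <- nuclear_total_ratio(imgr * 7.3, nuc, cell)$ratio
  expect_equal(r1, r2)

  expect_error(nuclear_total_ratio(img, array(FALSE, dim(img)), cell),
               "empty")
  nuc_out <- nuc; nuc_out[1, 1, 1] <- TRUE
  expect_error(nuclear_total_ratio(img, nuc_out, cell), "outside")
})

test_that("measured ratio decreases strictly with planted depletion", {
  ratios <- vapply(c(0, 0.25, 0.5, 0.75), function(d) {
    st <- gen_cell_stack(image_sim_params(n_cells = 5, depletion = d,
                                          noise_sd = 0.005, seed = 101))
    mean(nuclear_total_ratio(st$yfp, st$nucleus_mask, st$cell_mask)$ratio)
  }, 0)
  expect_true(all(diff(ratios) < 0))
  expect_lt(abs(ratios[1] - 1), 0.05)
})

test_that("mask derivation recovers planted cells and honors manual masks", {
  st <- gen_cell_stack(image_sim_params(n_cells = 5, seed = 103))
  m <- derive_masks(st$dye, st$yfp)
  truth <- st$nucleus_mask > 0
  iou <- sum(m$nucleus_mask & truth) / sum(m$nucleus_mask | truth)
  expect_gt(iou, 0.8)

  manual <- list(nucleus_mask = truth, cell_mask = st$cell_mask > 0)
  out <- derive_masks(st$dye, st$yfp, manual$nucleus_mask,
                      manual$cell_mask)
  expect_identical(out$nucleus_mask, manual$nucleus_mask)

  blank <- array(0.2, dim(st$dye))
  expect_error(derive_masks(blank, st$yfp), "constant|blank")
})

test_that("sectioned counting is exact for sub-spacing nuclei", {
  st <- gen_cell_stack(image_sim_params(ny = 256, nx = 256, nz = 15,
                                        n_cells = 50,
                                        nucleus_radius_um = 0.8,
                                        rim_width_um = 0.3,
                                        noise_sd = 0.005, seed = 107))
  cn <- count_nuclei(st$dye, z_step_um = 1, spacing_um = 2,
                     pixel_xy_um = 0.2)
  expect_equal(cn$count, 50L)

  empty <- count_nuclei(array(0, c(32, 32, 6)), z_step_um = 1)
  expect_equal(empty$count, 0L)

  big <- gen_cell_stack(image_sim_params(n_cells = 4,
                                         nucleus_radius_um = 1.5,
                                         noise_sd = 0.005, seed = 109))
  expect_warning(count_nuclei(big$dye, z_step_um = 1, spacing_um = 2,
                              pixel_xy_um = 0.2), "counted more than once")

  expect_error(count_nuclei(st$dye, z_step_um = NULL), "required")
})

test_that("background correction is exact in both modes", {
  lobe <- disc_mask(40, 40, 12, 12, 6)
  bg <- disc_mask(40, 40, 30, 30, 6)
  flat <- replicate(3, matrix(0.2, 40, 40), simplify = FALSE)
  expect_equal(background_corrected_intensity(flat, lobe, bg,
                                              "subtract")$value, 0)
  expect_equal(background_corrected_intensity(flat, lobe, bg,
                                              "ratio")$value, 1)

  twox <- lapply(flat, function(m) { m[lobe] <- 0.4; m })
  expect_equal(background_corrected_intensity(twox, lobe, bg,
                                              "ratio")$value, 2)

  expect_error(background_corrected_intensity(flat[1:2], lobe, bg),
               "three sections")
  expect_error(background_corrected_intensity(flat, lobe, lobe),
               "disjoint")
})

test_that("young-group normalization self-normalizes to mean 1", {
  set.seed(11)
  vals <- c(rnorm(6, 10), rnorm(6, 7))
  strat <- rep(c("g1.gamma", "g1.ab"), each = 6)
  young <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)
  nv <- normalize_to_young(vals, strat, young)
  expect_equal(mean(nv[strat == "g1.gamma" & young]), 1)
  expect_equal(mean(nv[strat == "g1.ab" & young]), 1)
})

test_that("contrast enhancement clips percentiles and fills the range", {
  const <- matrix(0.4, 10, 10)
  expect_identical(enhance_contrast(const), const)

  ramp <- matrix(seq(0, 1, length.out = 10000), 100, 100)
  out <- enhance_contrast(ramp, saturated = 0.02)
  q <- quantile(ramp, c(0.01, 0.99), names = FALSE)
  mid_in <- ramp > q[1] & ramp < q[2]
  expect_equal(out[mid_in], (ramp[mid_in] - q[1]) / (q[2] - q[1]))
  expect_equal(range(out), c(0, 1))
  expect_equal(mean(out == 0), 0.01, tolerance = 0.002)
})

test_that("Bernsen threshold equals per-pixel brute force", {
  set.seed(113)
  img <- matrix(runif(400), 20, 20)
  for (r in c(2, 4)) {
    for (ct in c(0.1, 0.5)) {
      expect_identical(bernsen_threshold(img, r, ct),
                       oracle_bernsen(img, r, ct))
    }
  }
  half <- cbind(matrix(0, 12, 6), matrix(1, 12, 6))
  expect_identical(bernsen_threshold(half, 3, 0.15),
                   oracle_bernsen(half, 3, 0.15))

  # uniform image: zero contrast everywhere, one class
  expect_true(all(bernsen_threshold(matrix(0.9, 15, 15), 3) |
                    !any(bernsen_threshold(matrix(0.9, 15, 15), 3))))
  u <- bernsen_threshold(matrix(0.9, 15, 15), 3)
  expect_true(all(u) || all(!u))

  disc <- matrix(0.05, 40, 40)
  disc[disc_mask(40, 40, 20, 20, 6)] <- 0.9
  got <- bernsen_threshold(disc, 10, 0.15)
  expect_true(all(got[disc_mask(40, 40, 20, 20, 4)]))

  expect_error(bernsen_threshold(img, 30), "larger than the image")
})

test_that("component labelling respects connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- TRUE   # touch diagonally
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  m[5, 5] <- TRUE
  expect_equal(max(label_components(m, 8)), 2L)
})

test_that("particle analysis applies inclusive size and shape filters", {
  sq <- matrix(FALSE, 10, 10); sq[4:5, 4:5] <- TRUE
  ap <- analyze_particles(sq, pixel_size_um = 0.5)
  expect_equal(ap$particles$area_um2, 1)
  expect_true(ap$particles$retained)

  tiny <- matrix(FALSE, 6, 6); tiny[3, 3] <- TRUE
  expect_false(analyze_particles(tiny, 0.1)$particles$retained)
  expect_equal(analyze_particles(tiny, 0.1)$particles$area_um2, 0.01)

  line <- matrix(FALSE, 5, 40); line[3, 3:32] <- TRUE
  apl <- analyze_particles(line, 0.2)
  expect_lt(apl$particles$circularity, 0.25)
  expect_false(apl$particles$retained)

  # inclusive at both area bounds: 25 px at 0.1 um/px = exactly 0.25 um^2
  lo <- matrix(FALSE, 12, 12); lo[4:8, 4:8] <- TRUE
  expect_true(analyze_particles(lo, 0.1)$particles$retained)
  # 12 px at 0.5 um/px = exactly 3.0 um^2
  hi <- matrix(FALSE, 10, 10); hi[4:6, 4:7] <- TRUE
  ap_hi <- analyze_particles(hi, 0.5)
  expect_equal(ap_hi$particles$area_um2, 3)
  expect_true(ap_hi$particles$retained)

  expect_error(analyze_particles(sq, pixel_size_um = NA), "uncalibrated")
})

test_that("chain-code perimeters match hand geometry", {
  rect <- matrix(FALSE, 8, 10); rect[3:5, 2:6] <- TRUE  # 3 x 5 block
  ap <- analyze_particles(rect, 1, area_bounds = c(0, 1e6),
                          circ_bounds = c(0, 1))
  expect_equal(ap$particles$perimeter_um, 2 * (2 + 4))
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_equal(analyze_particles(one, 1, area_bounds = c(0, 1e6),
                                 circ_bounds = c(0, 1))$particles$perimeter_um, 4)
})

test_that("planted puncta are recovered through the full pipeline", {
  pp <- data.frame(area_um2 = c(rep(1, 12), 5, 0.1),
                   eccentricity = c(rep(0, 13), 0))
  li <- gen_lobe_image(image_sim_params(ny = 220, nx = 220,
                                        pixel_xy_um = 0.1, puncta = pp,
                                        noise_sd = 0.01, seed = 127))
  en <- enhance_contrast(li$image)
  bw <- bernsen_threshold(en, radius = 8, contrast_threshold = 0.15)
  ap <- analyze_particles(bw, pixel_size_um = 0.1)
  expect_equal(nrow(ap$retained), 12L)  # 5 um^2 and 0.1 um^2 excluded
  expect_lt(abs(ap$mean_size - 1), 0.1)

  # an elongated streak fails the circularity filter on its own mask
  streak <- data.frame(area_um2 = 1.5, eccentricity = 0.999)
  ls <- gen_lobe_image(image_sim_params(ny = 120, nx = 120,
                                        pixel_xy_um = 0.1, puncta = streak,
                                        noise_sd = 0, seed = 131))
  aps <- analyze_particles(ls$mask > 0, pixel_size_um = 0.1)
  expect_lt(aps$particles$circularity[1], 0.25)
  expect_false(aps$particles$retained[1])
})
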