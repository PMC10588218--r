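#' Parameters for the confocal-image simulators
#'
#' One parameter object serves both image generators: [gen_cell_stack()]
#' renders a two-channel 3-D stack of cell bodies (nuclear-dye channel
#' plus a YFP channel whose nuclear signal can be depleted into the
#' cytoplasmic rim), and [gen_lobe_image()] renders a single 2-D lobe
#' section with planted puncta on a textured background.
#'
#' @param ny,nx,nz image dimensions (pixels / z-planes).
#' @param pixel_xy_um lateral pixel size (micrometres).
#' @param z_step_um axial plane spacing (micrometres).
#' @param n_cells number of cells to plant (cell-stack generator).
#' @param nucleus_radius_um,rim_width_um cell geometry (micrometres).
#' @param depletion fraction of nuclear YFP moved into the rim, in
#'   \[0, 1\]; 0 gives a uniform cell and a true nuclear/whole-cell ratio
#'   of 1.
#' @param background background level (image units in \[0, 1\]).
#' @param noise_sd Gaussian noise standard deviation.
#' @param z_snap_um nucleus z-centers are snapped to this grid so that a
#'   nucleus smaller than the counting-plane spacing intersects exactly
#'   one counting plane (set `NULL` to disable snapping).
#' @param puncta data.frame with columns `area_um2` and `eccentricity`,
#'   one row per punctum (lobe-image generator).
#' @param seed integer RNG seed.
#' @return object of class `image_sim_params`.
#' @export
image_sim_params <- function(ny = 128, nx = 128, nz = 16,
                             pixel_xy_um = 0.2, z_step_um = 1,
                             n_cells = 8, nucleus_radius_um = 1.5,
                             rim_width_um = 0.8, depletion = 0,
                             background = 0.05, noise_sd = 0.01,
                             z_snap_um = 2, puncta = NULL, seed = 1) {
  check_prob(depletion, "depletion")
  stopifnot(ny >= 8, nx >= 8, nz >= 1, pixel_xy_um > 0, z_step_um > 0,
            nucleus_radius_um > 0, rim_width_um > 0, noise_sd >= 0)
  structure(list(ny = ny, nx = nx, nz = nz, pixel_xy_um = pixel_xy_um,
                 z_step_um = z_step_um, n_cells = n_cells,
                 nucleus_radius_um = nucleus_radius_um,
                 rim_width_um = rim_width_um, depletion = depletion,
                 background = background, noise_sd = noise_sd,
                 z_snap_um = z_snap_um, puncta = puncta, seed = seed),
            class = "image_sim_params")
}

#' Simulate a two-channel cell-body stack with ground truth
#'
#' Nuclei are spheres, cytoplasm a concentric shell. The YFP channel
#' carries a uniform concentration per cell; a fraction `depletion` of the
#' nuclear amount is moved into the rim (conserving total signal), so the
#' true nuclear/whole-cell mean-intensity ratio decreases monotonically
#' with `depletion` and equals 1 at 0.
#'
#' @param params an [image_sim_params()] object.
#' @return list with `dye` and `yfp` (arrays \[ny, nx, nz\]),
#'   `nucleus_mask` and `cell_mask` (integer label arrays), `cells`
#'   (data.frame of planted centers and true intensities), and `params`.
#' @export
gen_cell_stack <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  r_nuc <- p$nucleus_radius_um
  r_cell <- r_nuc + p$rim_width_um
  r_cell_px <- ceiling(r_cell / p$pixel_xy_um)
  with_seed(stream_seed(p$seed, "image"), {
    dims <- c(p$ny, p$nx, p$nz)
    dye <- array(0, dims); yfp <- array(0, dims)
    nuc_lab <- array(0L, dims); cell_lab <- array(0L, dims)
    centers <- place_centers(p, r_cell_px)
    i0 <- 0.4
    for (i in seq_len(nrow(centers))) {
      cc <- centers[i, ]
      bb_y <- max(1, cc$cy - r_cell_px):min(p$ny, cc$cy + r_cell_px)
      bb_x <- max(1, cc$cx - r_cell_px):min(p$nx, cc$cx + r_cell_px)
      zr <- ceiling(r_cell / p$z_step_um)
      bb_z <- max(1, cc$cz - zr):min(p$nz, cc$cz + zr)
      g <- expand.grid(y = bb_y, x = bb_x, z = bb_z)
      d2 <- ((g$y - cc$cy) * p$pixel_xy_um)^2 +
        ((g$x - cc$cx) * p$pixel_xy_um)^2 +
        ((g$z - cc$cz) * p$z_step_um)^2
      in_nuc <- d2 <= r_nuc^2
      in_cell <- d2 <= r_cell^2
      idx <- cbind(g$y, g$x, g$z)
      v_nuc <- sum(in_nuc); v_rim <- sum(in_cell) - v_nuc
      if (v_nuc == 0L || v_rim == 0L) next
      i_nuc <- i0 * (1 - p$depletion)
      i_rim <- i0 * (1 + p$depletion * v_nuc / v_rim)
      nuc_lab[idx[in_nuc, , drop = FALSE]] <- i
      cell_lab[idx[in_cell, , drop = FALSE]] <- i
      dye[idx[in_nuc, , drop = FALSE]] <- 0.8
      yfp[idx[in_nuc, , drop = FALSE]] <- i_nuc
      yfp[idx[in_cell & !in_nuc, , drop = FALSE]] <- i_rim
    }
    dye <- clamp01(dye + p$background + stats::rnorm(length(dye), 0, p$noise_sd))
    yfp <- clamp01(yfp + p$background + stats::rnorm(length(yfp), 0, p$noise_sd))
    list(dye = dye, yfp = yfp, nucleus_mask = nuc_lab,
         cell_mask = cell_lab, cells = centers, params = p)
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

place_centers <- function(p, r_px, max_tries = 2000L) {
  zr <- ceiling((p$nucleus_radius_um + p$rim_width_um) / p$z_step_um)
  centers <- data.frame(cell_id = integer(0), cy = integer(0),
                        cx = integer(0), cz = integer(0))
  tries <- 0L
  while (nrow(centers) < p$n_cells && tries < max_tries) {
    tries <- tries + 1L
    cy <- sample(seq(r_px + 1L, p$ny - r_px), 1L)
    cx <- sample(seq(r_px + 1L, p$nx - r_px), 1L)
    zlo <- min(zr + 1L, p$nz); zhi <- max(p$nz - zr, zlo)
    cz <- sample(seq(zlo, zhi), 1L)
    if (!is.null(p$z_snap_um)) {
      grid_planes <- seq(1L, p$nz, by = max(1L, ceiling(p$z_snap_um / p$z_step_um)))
      cz <- grid_planes[which.min(abs(grid_planes - cz))]
    }
    if (nrow(centers) == 0L ||
        all((centers$cy - cy)^2 + (centers$cx - cx)^2 > (2L * r_px + 2L)^2 |
            abs(centers$cz - cz) > 2L * zr + 1L)) {
      centers <- rbind(centers,
                       data.frame(cell_id = nrow(centers) + 1L,
                                  cy = cy, cx = cx, cz = cz))
    }
  }
  if (nrow(centers) < p$n_cells) {
    stop("could not place ", p$n_cells, " non-overlapping cells; ",
         "enlarge the image or reduce n_cells")
  }
  centers
}

#' Simulate a lobe section with planted puncta
#'
#' Puncta are rendered as ellipses of specified area and eccentricity at
#' random non-overlapping positions and orientations, on a background with
#' a slow sinusoidal texture plus Gaussian noise — the substrate for
#' contrast enhancement, Bernsen thresholding and particle analysis.
#'
#' @param params an [image_sim_params()] object whose `puncta` field is a
#'   data.frame with columns `area_um2` and `eccentricity`.
#' @return list with `image` (matrix \[ny, nx\] in \[0, 1\]), `mask`
#'   (integer label matrix, ground truth), `puncta` (data.frame of planted
#'   centers, areas, eccentricities and rendered pixel areas), `params`.
#' @export
gen_lobe_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"),
            is.data.frame(params$puncta),
            all(c("area_um2", "eccentricity") %in% names(params$puncta)))
  p <- params
  with_seed(stream_seed(p$seed, "image"), {
    img <- matrix(0, p$ny, p$nx)
    lab <- matrix(0L, p$ny, p$nx)
    placed <- list()
    for (i in seq_len(nrow(p$puncta))) {
      area_px <- p$puncta$area_um2[i] / p$pixel_xy_um^2
      ecc <- p$puncta$eccentricity[i]
      q <- sqrt(1 - min(ecc, 0.999)^2)       # axis ratio b/a
      a <- sqrt(area_px / (pi * q)); b <- a * q
      theta <- stats::runif(1, 0, pi)
      margin <- ceiling(a) + 2L
      ok <- FALSE
      for (try in 1:500) {
        cy <- stats::runif(1, margin, p$ny - margin)
        cx <- stats::runif(1, margin, p$nx - margin)
        if (length(placed) == 0L ||
            all(vapply(placed, function(q0) {
              (q0$cy - cy)^2 + (q0$cx - cx)^2 > (q0$a + a + 3)^2
            }, TRUE))) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place punctum ", i, "; enlarge the image")
      bb_y <- floor(cy - margin):ceiling(cy + margin)
      bb_x <- floor(cx - margin):ceiling(cx + margin)
      g <- expand.grid(y = bb_y, x = bb_x)
      dy <- g$y - cy; dx <- g$x - cx
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      idx <- cbind(g$y, g$x)[inside, , drop = FALSE]
      img[idx] <- 0.85
      lab[idx] <- i
      placed[[i]] <- list(cy = cy, cx = cx, a = a,
                          pixel_area = nrow(idx))
    }
    tex <- 0.04 * outer(sin(seq_len(p$ny) / 17), cos(seq_len(p$nx) / 23))
    img <- clamp01(img + p$background + tex +
                     stats::rnorm(length(img), 0, p$noise_sd))
    pl <- do.call(rbind, lapply(seq_along(placed), function(i) {
      data.frame(punctum_id = i, cy = placed[[i]]$cy, cx = placed[[i]]$cx,
                 area_um2 = p$puncta$area_um2[i],
                 eccentricity = p$puncta$eccentricity[i],
                 pixel_area = placed[[i]]$pixel_area)
    }))
    list(image = img, mask = lab, puncta = pl, params = p)
  })
}

#' Write and read multi-page TIFF stacks
#'
#' Thin wrappers over the tiff package: a stack is an array
#' \[ny, nx, nz\] with values in \[0, 1\], stored one page per z-plane.
#'
#' @param stack array \[ny, nx, nz\] (a matrix is treated as one plane).
#' @param path file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   array \[ny, nx, nz\].
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3L]), function(z) stack[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  arr
}
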