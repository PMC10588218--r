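#' Percentile contrast enhancement
#'
#' Clips the image at the (s/2, 1 - s/2) intensity percentiles — 0.3% of
#' pixels saturated in total by default, split across both tails — and
#' rescales to the full \[0, 1\] range. A constant image is returned
#' unchanged.
#'
#' @param img numeric matrix or array.
#' @param saturated total fraction of pixels saturated (default 0.003).
#' @return image of the same shape, rescaled to \[0, 1\].
#' @export
enhance_contrast <- function(img, saturated = 0.003) {
  check_prob(saturated, "saturated")
  q <- stats::quantile(img, c(saturated / 2, 1 - saturated / 2),
                       names = FALSE)
  if (q[2L] <= q[1L]) return(img)
  out <- (img - q[1L]) / (q[2L] - q[1L])
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Bernsen local threshold
#'
#' Classic local adaptive thresholding: for each pixel, the local maximum
#' and minimum over a circular window of the given radius define a
#' midgray (max + min) / 2 and a local contrast (max - min). Where the
#' contrast reaches `contrast_threshold` the pixel is foreground iff its
#' value is at least the midgray; in low-contrast regions the whole
#' neighborhood is classified by comparing the midgray against the
#' global mid-intensity (bright-object-on-dark-background convention;
#' set `bright_background = TRUE` to invert). The contrast threshold
#' default corresponds to 15 intensity levels of an 8-bit image.
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param radius window radius in pixels (the source protocol used
#'   25-50 px depending on image quality).
#' @param contrast_threshold minimum local contrast (default 15/255).
#' @param bright_background if `TRUE`, low-contrast regions brighter than
#'   the global mid-intensity are background.
#' @return logical matrix, `TRUE` = foreground.
#' @export
bernsen_threshold <- function(img, radius = 15,
                              contrast_threshold = 15 / 255,
                              bright_background = FALSE) {
  stopifnot(is.matrix(img), radius >= 1)
  if (2 * radius + 1 > min(dim(img))) {
    stop("window radius larger than the image")
  }
  ext <- local_extrema(img, radius)
  mid <- (ext$max + ext$min) / 2
  contrast <- ext$max - ext$min
  global_mid <- (max(img) + min(img)) / 2
  low <- contrast < contrast_threshold
  fg <- img >= mid
  fg[low] <- if (bright_background) {
    mid[low] < global_mid
  } else {
    mid[low] >= global_mid
  }
  fg
}

# Local max/min over a circular window, by shifting the image over all
# in-disc offsets (window truncated at the image border).
local_extrema <- function(img, radius) {
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  ny <- nrow(img); nx <- ncol(img)
  mx <- img; mn <- img
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    if (dy == 0L && dx == 0L) next
    sh <- matrix(NA_real_, ny, nx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    sh[ys, xs] <- img[ys + dy, xs + dx]
    mx <- pmax(mx, sh, na.rm = TRUE)
    mn <- pmin(mn, sh, na.rm = TRUE)
  }
  list(max = mx, min = mn)
}

#' Label connected components
#'
#' 8-connected (default) or 4-connected component labelling of a binary
#' mask. The 4-connected pass is delegated to EBImage; 8-connectivity is
#' obtained by merging labels that touch diagonally.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background), labels
#'   consecutive from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  ny <- nrow(lab); nx <- ncol(lab)
  pairs <- NULL
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    y1 <- seq_len(ny - 1L); x1 <- if (d[2L] > 0) seq_len(nx - 1L) else 2:nx
    a <- lab[y1, x1, drop = FALSE]
    b <- lab[y1 + 1L, x1 + d[2L], drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  parent <- seq_len(max(lab))
  if (!is.null(pairs)) {
    # union-find over diagonal-touching label pairs
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    parent <- vapply(seq_along(parent), find, 0L)
  }
  occ <- sort(unique(parent[unique(lab[lab > 0L])]))
  out <- matrix(0L, ny, nx)
  nz <- lab > 0L
  out[nz] <- match(parent[lab[nz]], occ)
  out
}

# Moore-neighbor boundary trace of one 8-connected component; returns the
# chain-code perimeter (straight steps 1, diagonal steps sqrt(2)).
# Single-pixel components get the square-outline convention (perimeter 4).
# Directions are clockwise from West; after a move in direction k the next
# scan starts at (k + 6) mod 8, and tracing stops on Jacob's criterion
# (the start pixel is re-entered and the next move repeats the first).
chain_perimeter <- function(comp) {
  pix <- which(comp, arr.ind = TRUE)
  if (nrow(pix) == 1L) return(4)
  ny <- nrow(comp); nx <- ncol(comp)
  # 0-based clockwise dirs: W, NW, N, NE, E, SE, S, SW
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  len <- ifelse(abs(dy) + abs(dx) == 2L, sqrt(2), 1)
  inside <- function(y, x) y >= 1L && y <= ny && x >= 1L && x <= nx &&
    comp[y, x]
  next_dir <- function(y, x, from) {
    for (s in 0:7) {
      k <- (from + s) %% 8L
      if (inside(y + dy[k + 1L], x + dx[k + 1L])) return(k)
    }
    -1L
  }
  start <- pix[order(pix[, 1L], pix[, 2L]), , drop = FALSE][1L, ]
  sy <- start[[1L]]; sx <- start[[2L]]
  first <- next_dir(sy, sx, 0L)  # west neighbor of start is background
  if (first < 0L) return(4)
  per <- len[first + 1L]
  cy <- sy + dy[first + 1L]; cx <- sx + dx[first + 1L]
  scan <- (first + 6L) %% 8L
  max_steps <- 4L * nrow(pix) + 8L
  for (step in seq_len(max_steps)) {
    if (cy == sy && cx == sx && next_dir(cy, cx, scan) == first) {
      return(max(per, 4))
    }
    k <- next_dir(cy, cx, scan)
    per <- per + len[k + 1L]
    cy <- cy + dy[k + 1L]; cx <- cx + dx[k + 1L]
    scan <- (k + 6L) %% 8L
  }
  max(per, 4)  # safety stop
}

#' Particle (puncta) analysis with size and circularity filters
#'
#' Labels 8-connected components of a thresholded mask, measures each
#' particle's calibrated area, chain-code perimeter and circularity
#' 4*pi*area/perimeter^2 (clamped to 1), and retains particles whose
#' area and circularity fall inclusively within the given bounds —
#' 0.25-3.0 square micrometres and 0.25-1.0 circularity, the puncta
#' definition.
#'
#' @param mask logical matrix (foreground = candidate particles).
#' @param pixel_size_um lateral pixel size in micrometres (required:
#'   an uncalibrated image is an error).
#' @param area_bounds inclusive area bounds, square micrometres.
#' @param circ_bounds inclusive circularity bounds.
#' @return list with `particles` (data.frame particle_id, area_um2,
#'   perimeter_um, circularity, retained), `retained` (subset), and
#'   `mean_size` (mean retained area, NA when none).
#' @export
analyze_particles <- function(mask, pixel_size_um,
                              area_bounds = c(0.25, 3.0),
                              circ_bounds = c(0.25, 1.0)) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("uncalibrated image: pixel_size_um is required")
  }
  stopifnot(is.matrix(mask))
  lab <- label_components(mask, connectivity = 8L)
  n <- max(lab)
  if (n == 0L) {
    empty <- data.frame(particle_id = integer(0), area_um2 = numeric(0),
                        perimeter_um = numeric(0), circularity = numeric(0),
                        retained = logical(0))
    return(list(particles = empty, retained = empty, mean_size = NA_real_))
  }
  rows <- lapply(seq_len(n), function(id) {
    sel <- which(lab == id, arr.ind = TRUE)
    bb <- matrix(FALSE,
                 diff(range(sel[, 1L])) + 1L, diff(range(sel[, 2L])) + 1L)
    bb[cbind(sel[, 1L] - min(sel[, 1L]) + 1L,
             sel[, 2L] - min(sel[, 2L]) + 1L)] <- TRUE
    per_px <- chain_perimeter(bb)
    area <- nrow(sel) * pixel_size_um^2
    per <- per_px * pixel_size_um
    circ <- min(1, 4 * pi * area / per^2)
    data.frame(particle_id = id, area_um2 = area, perimeter_um = per,
               circularity = circ)
  })
  df <- do.call(rbind, rows)
  df$retained <- df$area_um2 >= area_bounds[1L] &
    df$area_um2 <= area_bounds[2L] &
    df$circularity >= circ_bounds[1L] & df$circularity <= circ_bounds[2L]
  ret <- df[df$retained, , drop = FALSE]
  list(particles = df, retained = ret,
       mean_size = if (nrow(ret)) mean(ret$area_um2) else NA_real_)
}

#' Mean particle size across sections
#'
#' Mean of per-section mean retained areas (>= 3 sections per lobe), the
#' per-lobe summary from which a per-brain mean is taken.
#'
#' @param particle_sets list of [analyze_particles()] results, one per
#'   section.
#' @return mean of per-section `mean_size` values (sections with no
#'   retained particles are dropped).
#' @export
mean_particle_size <- function(particle_sets) {
  sizes <- vapply(particle_sets, function(p) p$mean_size, 0)
  sizes <- sizes[is.finite(sizes)]
  if (!length(sizes)) return(NA_real_)
  mean(sizes)
}
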