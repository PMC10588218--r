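#' Nuclear to whole-cell intensity ratio
#'
#' Ratio of the mean YFP intensity inside the nucleus to the mean over
#' the whole cell, the nuclear-depletion readout. Masks may be logical
#' (one cell) or integer label images (one row per cell; nucleus and cell
#' labels must correspond). The ratio is scale-invariant and may exceed 1
#' for punctate nuclear signal.
#'
#' @param yfp image array (2-D or 3-D).
#' @param nucleus_mask,cell_mask logical or integer-label arrays of the
#'   same dimensions as `yfp`; every nucleus must lie inside its cell.
#' @return data.frame with `cell_id`, `nuclear_mean`, `whole_cell_mean`,
#'   `ratio`.
#' @export
nuclear_total_ratio <- function(yfp, nucleus_mask, cell_mask) {
  stopifnot(all(dim(yfp) == dim(nucleus_mask)),
            all(dim(yfp) == dim(cell_mask)))
  if (is.logical(nucleus_mask)) nucleus_mask <- nucleus_mask * 1L
  if (is.logical(cell_mask)) cell_mask <- cell_mask * 1L
  ids <- sort(unique(nucleus_mask[nucleus_mask > 0]))
  if (length(ids) == 0L) stop("empty nucleus mask")
  if (any(cell_mask[nucleus_mask > 0] == 0)) {
    stop("nucleus mask extends outside the cell mask")
  }
  out <- lapply(ids, function(id) {
    nuc <- nucleus_mask == id
    cell <- cell_mask == id
    if (!any(cell)) stop("empty cell mask for cell ", id)
    if (any(nuc & !cell)) {
      stop("nucleus ", id, " extends outside cell ", id)
    }
    nm <- mean(yfp[nuc]); wm <- mean(yfp[cell])
    data.frame(cell_id = id, nuclear_mean = nm, whole_cell_mean = wm,
               ratio = if (wm > 0) nm / wm else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Derive nucleus and cell masks from the two channels
#'
#' Optional automation of the manual tracing step: a global Otsu
#' threshold on the nuclear-dye channel gives the nucleus mask, and an
#' Otsu threshold on the YFP channel followed by hole filling gives the
#' cell mask (forced to contain the nucleus mask). Manually supplied
#' masks always take precedence and pass through unchanged.
#'
#' @param hoechst,yfp image arrays of equal dimensions.
#' @param nucleus_mask,cell_mask optional manual masks; if both are given
#'   they are returned as-is.
#' @return list with logical `nucleus_mask` and `cell_mask`.
#' @export
derive_masks <- function(hoechst, yfp, nucleus_mask = NULL,
                         cell_mask = NULL) {
  if (!is.null(nucleus_mask) && !is.null(cell_mask)) {
    return(list(nucleus_mask = nucleus_mask, cell_mask = cell_mask))
  }
  stopifnot(all(dim(hoechst) == dim(yfp)))
  if (is.null(nucleus_mask)) {
    nucleus_mask <- hoechst > otsu_threshold(hoechst)
    if (!any(nucleus_mask)) stop("no nuclear mask: dye channel is blank")
  }
  if (is.null(cell_mask)) {
    cm <- yfp > otsu_threshold(yfp)
    if (!any(cm)) stop("no cell mask: YFP channel is blank")
    cm <- fill_mask_holes(cm)
    cell_mask <- cm | nucleus_mask
  }
  list(nucleus_mask = nucleus_mask, cell_mask = cell_mask)
}

# Global Otsu threshold over all voxels (EBImage's implementation, fed
# the flattened intensity values as a single frame).
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  if (max(v) <= min(v)) stop("cannot threshold a constant image")
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)), range = range(v))
}

fill_mask_holes <- function(mask) {
  if (length(dim(mask)) == 3L) {
    for (z in seq_len(dim(mask)[3L])) {
      mask[, , z] <- EBImage::fillHull(mask[, , z] * 1L) > 0
    }
    mask
  } else {
    EBImage::fillHull(mask * 1L) > 0
  }
}

#' Count nuclei from optical sections a fixed distance apart
#'
#' Selects z-planes at least `spacing_um` apart (every
#' `ceiling(spacing_um / z_step_um)`-th plane starting at the first),
#' thresholds the nuclear-dye channel globally (Otsu unless a threshold
#' is supplied), counts 8-connected components of at least `min_px`
#' pixels in each selected plane, and sums over planes. The spacing
#' guarantees each nucleus smaller than the spacing is sectioned by at
#' most one counting plane; a warning is issued when the detected nuclei
#' look larger than the spacing (double counting possible).
#'
#' @param stack 3-D dye-channel array \[ny, nx, nz\].
#' @param z_step_um axial plane spacing of the stack (required).
#' @param spacing_um minimum distance between counting planes (default 2).
#' @param pixel_xy_um lateral pixel size, used only for the size warning.
#' @param threshold optional global threshold; default Otsu.
#' @param min_px minimum component size in pixels (speckle guard).
#' @return list with `count` (total), `per_plane` (data.frame plane,
#'   count), `threshold`.
#' @export
count_nuclei <- function(stack, z_step_um, spacing_um = 2,
                         pixel_xy_um = NULL, threshold = NULL,
                         min_px = 4L) {
  if (missing(z_step_um) || is.null(z_step_um) || is.na(z_step_um)) {
    stop("z-plane spacing (z_step_um) is required")
  }
  stopifnot(length(dim(stack)) == 3L, z_step_um > 0, spacing_um > 0)
  sel <- seq(1L, dim(stack)[3L], by = max(1L, ceiling(spacing_um / z_step_um)))
  if (is.null(threshold)) {
    threshold <- tryCatch(otsu_threshold(stack), error = function(e) Inf)
  }
  diam_um <- numeric(0)
  per_plane <- lapply(sel, function(z) {
    mask <- stack[, , z] > threshold
    lab <- label_components(mask, connectivity = 8L)
    sizes <- tabulate(lab[lab > 0])
    sizes <- sizes[sizes >= min_px]
    if (!is.null(pixel_xy_um) && length(sizes)) {
      diam_um <<- c(diam_um, 2 * sqrt(sizes / pi) * pixel_xy_um)
    }
    data.frame(plane = z, count = length(sizes))
  })
  per_plane <- do.call(rbind, per_plane)
  if (length(diam_um) && stats::median(diam_um) > spacing_um) {
    warning("median nucleus diameter (", round(stats::median(diam_um), 2),
            " um) exceeds the section spacing (", spacing_um,
            " um): nuclei may be counted more than once")
  }
  list(count = sum(per_plane$count), per_plane = per_plane,
       threshold = threshold)
}

#' Background-corrected lobe intensity
#'
#' Per optical section, either the integrated density of the lobe region
#' minus the adjacent-background mean times the lobe area (`mode =
#' "subtract"`, the FITC/RFP convention) or the lobe mean divided by the
#' background mean (`mode = "ratio"`); the reported value is the mean
#' over sections. At least three sections are required and the two
#' regions must be disjoint.
#'
#' @param sections list of 2-D matrices or a 3-D array of >= 3 sections.
#' @param lobe_roi,background_roi logical masks (2-D, shared by all
#'   sections), disjoint.
#' @param mode "subtract" or "ratio".
#' @return list with `value` (mean over sections), `per_section`, `mode`.
#' @export
background_corrected_intensity <- function(sections, lobe_roi,
                                           background_roi,
                                           mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  if (is.array(sections) && length(dim(sections)) == 3L) {
    sections <- lapply(seq_len(dim(sections)[3L]),
                       function(z) sections[, , z])
  }
  if (length(sections) < 3L) stop("need at least three sections")
  stopifnot(is.logical(lobe_roi), is.logical(background_roi))
  if (any(lobe_roi & background_roi)) {
    stop("lobe and background ROIs must be disjoint")
  }
  if (!any(lobe_roi) || !any(background_roi)) stop("empty ROI")
  per <- vapply(sections, function(img) {
    stopifnot(all(dim(img) == dim(lobe_roi)))
    bg <- mean(img[background_roi])
    if (mode == "subtract") {
      sum(img[lobe_roi]) - bg * sum(lobe_roi)
    } else {
      if (bg <= 0) stop("background mean is zero; ratio undefined")
      mean(img[lobe_roi]) / bg
    }
  }, 0)
  list(value = mean(per), per_section = per, mode = mode)
}

#' Normalize intensities to the young-group mean
#'
#' Divides each value by the mean of the young (reference) measurements
#' within the same stratum (genotype x lobe). By construction, the mean
#' normalized value of each stratum's young group is exactly 1.
#'
#' @param values numeric measurements.
#' @param stratum labels defining the normalization stratum.
#' @param is_young logical: reference (young) measurements.
#' @return numeric vector of normalized values.
#' @export
normalize_to_young <- function(values, stratum, is_young) {
  stopifnot(length(values) == length(stratum),
            length(values) == length(is_young))
  out <- numeric(length(values))
  for (g in unique(stratum)) {
    sel <- stratum == g
    ref <- mean(values[sel & is_young])
    if (!is.finite(ref) || ref == 0) {
      stop("no usable young reference for stratum ", g)
    }
    out[sel] <- values[sel] / ref
  }
  out
}
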