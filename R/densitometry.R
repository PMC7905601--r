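#' Regions of interest in physical (mm) coordinates
#'
#' ROIs live in millimetre coordinates with the origin at the image's
#' top-left corner; pixel centers sit at `(index - 0.5) * pixel_size`.
#' `roi_square()` is the fixed-size square used for optical-density
#' readings (default side 0.2 mm); `roi_polygon()` is a delineated border.
#'
#' @param center numeric `c(x, y)` in mm.
#' @param side side length in mm (> 0).
#' @return an object of class `roi`.
#' @export
roi_square <- function(center, side = 0.2) {
  if (side <= 0) ss_stop("invalid_argument", "square side must be > 0")
  structure(list(kind = "square", center = as.numeric(center), side = side),
            class = "roi")
}

#' @rdname roi_square
#' @param vertices two-column matrix of polygon vertices (x, y) in mm.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L) {
    ss_stop("invalid_argument", "a polygon needs at least 3 (x, y) vertices")
  }
  structure(list(kind = "polygon", vertices = vertices), class = "roi")
}

roi_bbox <- function(roi) {
  if (roi$kind == "square") {
    h <- roi$side / 2
    c(roi$center[1] - h, roi$center[2] - h, roi$center[1] + h, roi$center[2] + h)
  } else {
    c(min(roi$vertices[, 1]), min(roi$vertices[, 2]),
      max(roi$vertices[, 1]), max(roi$vertices[, 2]))
  }
}

translate_roi <- function(roi, offset) {
  if (roi$kind == "square") {
    roi$center <- roi$center + offset
  } else {
    roi$vertices <- sweep(roi$vertices, 2, offset, "+")
  }
  roi
}

# Logical mask of pixels whose centers fall inside the roi.
roi_mask <- function(image, roi, pixel_size_mm) {
  nr <- nrow(image)
  nc <- ncol(image)
  cx <- (seq_len(nc) - 0.5) * pixel_size_mm
  cy <- (seq_len(nr) - 0.5) * pixel_size_mm
  if (roi$kind == "square") {
    h <- roi$side / 2
    outer(abs(cy - roi$center[2]) <= h, abs(cx - roi$center[1]) <= h, "&")
  } else {
    pts <- cbind(rep(cx, each = nr), rep(cy, times = nc))
    matrix(mgcv::in.out(rbind(roi$vertices, roi$vertices[1, ]), pts), nrow = nr)
  }
}

#' Mean grey value inside a region of interest
#'
#' @param image numeric matrix of grey values (rows = y, columns = x).
#' @param roi a [roi_square()] or [roi_polygon()].
#' @param pixel_size_mm physical pixel size, mm/pixel.
#' @return mean grey value over pixels whose centers fall inside `roi`.
#' @export
mean_od <- function(image, roi, pixel_size_mm) {
  stopifnot(inherits(roi, "roi"), pixel_size_mm > 0)
  m <- roi_mask(image, roi, pixel_size_mm)
  if (!any(m)) ss_stop("invalid_argument", "roi covers no pixel center")
  mean(image[m])
}

#' Background-subtracted optical density
#'
#' Net OD is the region reading minus that of an adjacent control area.
#' Negative values are retained (they indicate a region darker than its
#' background) and flagged via the `"flagged"` attribute.
#'
#' @param region_od,background_od mean grey values.
#' @return net OD (`region_od - background_od`).
#' @export
background_subtract <- function(region_od, background_od) {
  if (!is.finite(region_od) || !is.finite(background_od)) {
    ss_stop("invalid_argument", "both OD values must be finite")
  }
  net <- region_od - background_od
  if (net < 0) attr(net, "flagged") <- TRUE
  net
}

#' Delineate an expression region
#'
#' Automated stand-in for manual border tracing: pixels brighter than the
#' background mean plus `c` background standard deviations (background
#' estimated from the image's border frame) are thresholded, the mask is
#' morphologically closed, and the largest connected component is returned
#' as a boundary polygon. Its area (`area_mm2` field) is the pixel count of
#' the component times the pixel area. Ties between equally large blobs are
#' broken leftmost-first.
#'
#' @param image numeric matrix of grey values.
#' @param pixel_size_mm physical pixel size, mm/pixel.
#' @param c threshold constant (background mean + `c` * background SD).
#' @param close_px radius of the disc structuring element for morphological
#'   closing, pixels.
#' @param border_frac fraction of each image edge used to estimate the
#'   background.
#' @return a polygon `roi` with extra fields `area_mm2`, `n_pixels`,
#'   `n_blobs`, `threshold`.
#' @export
delineate_region <- function(image, pixel_size_mm, c = 3, close_px = 2,
                             border_frac = 0.1) {
  nr <- nrow(image)
  nc <- ncol(image)
  bw <- max(1L, round(border_frac * min(nr, nc)))
  border <- rbind(image[c(seq_len(bw), nr - seq_len(bw) + 1L), , drop = FALSE],
                  t(image[, c(seq_len(bw), nc - seq_len(bw) + 1L), drop = FALSE]))
  thr <- mean(border) + c * stats::sd(border)
  mask <- image > thr
  if (!any(mask)) {
    ss_stop("not_found", "no supra-threshold region in image", list(threshold = thr))
  }
  # EBImage indexes images [x, y]; transpose in and out
  m <- EBImage::Image(t(mask))
  if (close_px > 0) {
    m <- EBImage::closing(m, EBImage::makeBrush(2L * close_px + 1L, shape = "disc"))
  }
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(as.integer(lab))
  if (length(sizes) == 0L) ss_stop("not_found", "no connected component after closing")
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {   # leftmost wins
    leftmost <- vapply(biggest, function(i) {
      min(which(apply(lab == i, 1, any)))
    }, numeric(1))
    biggest <- biggest[which.min(leftmost)]
  }
  comp <- lab == biggest[1]
  contour <- EBImage::ocontour(EBImage::Image(comp))[[1]]
  roi <- roi_polygon((contour + 0.5) * pixel_size_mm)
  roi$area_mm2 <- sum(comp) * pixel_size_mm^2
  roi$n_pixels <- sum(comp)
  roi$n_blobs <- length(sizes)
  roi$threshold <- thr
  roi
}

#' Nucleus volume from serial-section areas
#'
#' The classic serial-section estimator: delineated areas are summed and
#' multiplied by the spacing between analyzed sections (default 0.2 mm).
#'
#' @param areas numeric vector of per-section areas, mm^2 (all >= 0).
#' @param spacing_mm distance between analyzed sections, mm.
#' @return an object of class `volume_estimate`: list with `areas`,
#'   `spacing_mm`, `volume_mm3`.
#' @export
nucleus_volume <- function(areas, spacing_mm = 0.2) {
  if (length(areas) == 0L) ss_stop("invalid_argument", "need at least one section area")
  if (any(!is.finite(areas)) || any(areas < 0)) {
    ss_stop("invalid_argument", "areas must be finite and >= 0")
  }
  if (spacing_mm <= 0) ss_stop("invalid_argument", "spacing_mm must be > 0")
  structure(list(areas = areas, spacing_mm = spacing_mm,
                 volume_mm3 = sum(areas) * spacing_mm),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate> %.4f mm^3 from %d sections (spacing %.2f mm)\n",
              x$volume_mm3, length(x$areas), x$spacing_mm))
  invisible(x)
}

#' Average replicate volume estimates
#'
#' The delineation protocol is run several times (three by default) and the
#' resulting volumes averaged to one final figure per individual.
#'
#' @param replicates list of [nucleus_volume()] results (>= 1).
#' @return list of class `replicate_volume`: `volumes`, `mean_volume_mm3`,
#'   `cv` (coefficient of variation across replicates).
#' @export
replicate_volume <- function(replicates) {
  if (length(replicates) == 0L) ss_stop("invalid_argument", "need at least one replicate")
  stopifnot(all(vapply(replicates, inherits, logical(1), "volume_estimate")))
  v <- vapply(replicates, function(r) r$volume_mm3, numeric(1))
  structure(list(volumes = v, mean_volume_mm3 = mean(v),
                 cv = if (mean(v) > 0) stats::sd(v) / mean(v) else 0),
            class = "replicate_volume")
}

#' Triplicate delineation of a section stack
#'
#' Runs [delineate_region()] on every section of a stack `n_replicates`
#' times, jittering the delineation threshold constant between replicates
#' (emulating between-tracing variability), and averages the resulting
#' volumes with [replicate_volume()].
#'
#' @param stack a `section_stack` (see [synth_section_stack()] or
#'   [read_section_stack()]).
#' @param c base threshold constant.
#' @param n_replicates number of delineation passes.
#' @param c_jitter standard deviation of the per-replicate jitter on `c`.
#' @param seed integer seed for the jitter.
#' @return a `replicate_volume`, with the per-replicate
#'   [nucleus_volume()] objects in `$replicates`.
#' @export
measure_nucleus_volume <- function(stack, c = 3, n_replicates = 3, c_jitter = 0.25,
                                   seed = 1L) {
  stopifnot(inherits(stack, "section_stack"))
  cs <- with_seed(seed, c + stats::rnorm(n_replicates, sd = c_jitter))
  reps <- lapply(cs, function(ci) {
    areas <- vapply(stack$sections, function(img) {
      delineate_region(img, stack$pixel_size_mm, c = ci)$area_mm2
    }, numeric(1))
    nucleus_volume(areas, stack$spacing_mm)
  })
  out <- replicate_volume(reps)
  out$replicates <- reps
  out
}

#' Expression profile of a region across a section stack
#'
#' Per section, reads the mean grey value in the region ROI, subtracts the
#' mean of an equal-area control ROI placed adjacent to it (translated by
#' `background_offset_mm`), then averages net OD across sections.
#'
#' @param stack a `section_stack`.
#' @param roi region ROI (applied to every section), or a list with one ROI
#'   per section.
#' @param background_offset_mm numeric `c(dx, dy)` translation from region
#'   to control area, mm.
#' @return list of class `od_result`: `region_od`, `background_od`,
#'   `net_od` (cross-section means), `n_sections`, `per_section` (data
#'   frame `section`, `region_od`, `background_od`, `net_od`).
#' @export
expression_profile <- function(stack, roi, background_offset_mm) {
  stopifnot(inherits(stack, "section_stack"))
  n <- length(stack$sections)
  rois <- if (inherits(roi, "roi")) rep(list(roi), n) else roi
  stopifnot(length(rois) == n)
  psz <- stack$pixel_size_mm
  rows <- lapply(seq_len(n), function(i) {
    img <- stack$sections[[i]]
    bg_roi <- translate_roi(rois[[i]], background_offset_mm)
    bb <- roi_bbox(bg_roi)
    if (bb[1] < 0 || bb[2] < 0 || bb[3] > ncol(img) * psz || bb[4] > nrow(img) * psz) {
      ss_stop("invalid_argument",
              sprintf("background ROI falls off section %d; choose another offset", i))
    }
    r_od <- mean_od(img, rois[[i]], psz)
    b_od <- mean_od(img, bg_roi, psz)
    data.frame(section = i, region_od = r_od, background_od = b_od,
               net_od = as.numeric(background_subtract(r_od, b_od)))
  })
  per_section <- do.call(rbind, rows)
  structure(
    list(region_od = mean(per_section$region_od),
         background_od = mean(per_section$background_od),
         net_od = mean(per_section$net_od),
         n_sections = n, per_section = per_section),
    class = "od_result"
  )
}

#' @export
print.od_result <- function(x, ...) {
  cat(sprintf("<od_result> net OD %.3f (region %.3f - background %.3f, %d sections)\n",
              x$net_od, x$region_od, x$background_od, x$n_sections))
  invisible(x)
}
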