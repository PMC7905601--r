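#' Synthesize an autoradiogram section stack with known ground truth
#'
#' Each section is a uniform background plus an added signal inside a
#' circular region (a cylinder through the stack, the simplest nucleus
#' phantom), plus optional Gaussian pixel noise. The true volume recorded in
#' the ground truth is the rasterized mask area summed over sections times
#' the section spacing.
#'
#' @param radius_mm cylinder radius, mm (0 gives empty masks and zero
#'   volume).
#' @param n_sections number of sections in the stack.
#' @param pixel_size_mm physical pixel size, mm/pixel.
#' @param spacing_mm distance between analyzed sections, mm (default 0.2).
#' @param background background grey value.
#' @param signal added grey value inside the region (> 0).
#' @param noise_sd Gaussian pixel noise SD (0 for noiseless).
#' @param img_px image size `c(rows, cols)` in pixels.
#' @param center_mm region center `c(x, y)` in mm; defaults to the image
#'   center.
#' @param seed integer seed for the noise.
#' @return an object of class `section_stack`: list with `sections` (list
#'   of matrices), `pixel_size_mm`, `spacing_mm`, and `truth` (list with
#'   `masks`, `net_signal`, `volume_mm3`, `radius_mm`, `center_mm`).
#' @export
synth_section_stack <- function(radius_mm = 0.5, n_sections = 5, pixel_size_mm = 0.02,
                                spacing_mm = 0.2, background = 100, signal = 40,
                                noise_sd = 0, img_px = c(128, 128), center_mm = NULL,
                                seed = 1L) {
  if (signal <= 0) ss_stop("invalid_spec", "signal must be > 0")
  if (radius_mm < 0) ss_stop("invalid_spec", "radius_mm must be >= 0")
  if (!is_count(n_sections) || n_sections < 1) {
    ss_stop("invalid_spec", "n_sections must be an integer >= 1")
  }
  nr <- img_px[1]
  nc <- img_px[2]
  ext <- c(nc, nr) * pixel_size_mm
  center_mm <- center_mm %||% (ext / 2)
  if (center_mm[1] - radius_mm < 0 || center_mm[2] - radius_mm < 0 ||
      center_mm[1] + radius_mm > ext[1] || center_mm[2] + radius_mm > ext[2]) {
    ss_stop("invalid_spec", "region does not fit inside the image")
  }
  cx <- (seq_len(nc) - 0.5) * pixel_size_mm
  cy <- (seq_len(nr) - 0.5) * pixel_size_mm
  mask <- outer((cy - center_mm[2])^2, (cx - center_mm[1])^2, "+") <= radius_mm^2
  sections <- with_seed(seed, lapply(seq_len(n_sections), function(i) {
    img <- matrix(background, nr, nc) + signal * mask
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
    img
  }))
  structure(
    list(sections = sections, pixel_size_mm = pixel_size_mm, spacing_mm = spacing_mm,
         truth = list(masks = rep(list(mask), n_sections), net_signal = signal,
                      volume_mm3 = n_sections * sum(mask) * pixel_size_mm^2 * spacing_mm,
                      radius_mm = radius_mm, center_mm = center_mm)),
    class = "section_stack"
  )
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d sections of %d x %d px | %.3f mm/px, spacing %.2f mm\n",
              length(x$sections), nrow(x$sections[[1]]), ncol(x$sections[[1]]),
              x$pixel_size_mm, x$spacing_mm))
  invisible(x)
}

#' Write and read a section stack as PGM + JSON metadata
#'
#' Sections are stored as plain (ASCII, P2) PGM images, rounded to 16-bit
#' integers, together with a `metadata.json` file carrying `pixel_size_mm`
#' and `spacing_mm`. Ground-truth information is not serialized.
#'
#' @param stack a `section_stack`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a `section_stack` (read), invisibly for write.
#' @export
write_section_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "section_stack"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    ss_stop("io", sprintf("cannot create '%s'", dir))
  }
  for (i in seq_along(stack$sections)) {
    img <- pmin(pmax(round(stack$sections[[i]]), 0), 65535)
    path <- file.path(dir, sprintf("section_%03d.pgm", i))
    con <- file(path, "w")
    writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "65535"), con)
    write(t(img), file = con, ncolumns = 16)
    close(con)
  }
  jsonlite::write_json(
    list(pixel_size_mm = stack$pixel_size_mm, spacing_mm = stack$spacing_mm,
         n_sections = length(stack$sections)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_section_stack
#' @export
read_section_stack <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) ss_stop("io", sprintf("no metadata.json in '%s'", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^section_\\d+\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) ss_stop("io", sprintf("no section PGMs in '%s'", dir))
  sections <- lapply(files, function(f) {
    tok <- scan(f, what = character(), quiet = TRUE, comment.char = "#")
    if (tok[1] != "P2") ss_stop("io", sprintf("'%s' is not a plain (P2) PGM", f))
    w <- as.integer(tok[2])
    h <- as.integer(tok[3])
    matrix(as.numeric(tok[-(1:4)]), nrow = h, ncol = w, byrow = TRUE)
  })
  structure(list(sections = sections, pixel_size_mm = meta$pixel_size_mm,
                 spacing_mm = meta$spacing_mm, truth = NULL),
            class = "section_stack")
}
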