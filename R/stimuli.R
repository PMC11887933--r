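#' @title Stimulus geometry and rasterization
#' @name stimuli
#' @description
#' Declarative geometry (in visual degrees) and rasterization of the eight
#' vernier/flanker/Pacman configurations used in the crowding/uncrowding
#' battery. All coordinates are measured from the stimulus centre, x
#' rightward, y downward; the fixation point lies outside the simulated
#' patch (the 10.5 deg eccentricity is metadata, not rendered).
NULL

#' Names of the eight stimulus conditions
#'
#' @return Character vector of the eight supported condition names.
#' @export
condition_names <- function() {
  c("VERNIER_ONLY", "EQUAL_FLANKERS", "LONG", "GAPPED",
    "GAPPED_INWARD", "GAPPED_OUTWARD", "LONG_INWARD", "LONG_OUTWARD")
}

#' Display configuration
#'
#' Geometry of the simulated display patch. Luminances are fractions of the
#' monitor maximum: light grey background (0.75) with dark grey (0.25)
#' elements.
#'
#' @param viewing_distance_cm Viewing distance in cm (metadata only).
#' @param pixels_per_degree Raster resolution (pixels per visual degree).
#' @param background_luminance Background luminance fraction in `[0, 1]`.
#' @param element_luminance Element luminance fraction; must be strictly
#'   below `background_luminance`.
#' @param field_width_deg,field_height_deg Extent of the simulated patch,
#'   centred on the stimulus, in degrees.
#' @return An object of class `display_config`.
#' @export
display_config <- function(viewing_distance_cm = 55,
                           pixels_per_degree = 10,
                           background_luminance = 0.75,
                           element_luminance = 0.25,
                           field_width_deg = 16,
                           field_height_deg = 14) {
  stopifnot(
    is.numeric(pixels_per_degree), length(pixels_per_degree) == 1L,
    pixels_per_degree > 0,
    element_luminance >= 0, background_luminance <= 1,
    element_luminance < background_luminance,
    field_width_deg > 0, field_height_deg > 0
  )
  structure(list(
    viewing_distance_cm = viewing_distance_cm,
    pixels_per_degree = pixels_per_degree,
    background_luminance = background_luminance,
    element_luminance = element_luminance,
    field_width_deg = field_width_deg,
    field_height_deg = field_height_deg
  ), class = "display_config")
}

#' Round half away from zero
#'
#' The pixel-rounding convention used throughout: `0.5 -> 1`, `-0.5 -> -1`.
#' Symmetric under negation, which keeps left/right mirror renders exact.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a degree coordinate to a pixel index
#'
#' Pixel indices are integer offsets from the image origin (the pixel at the
#' stimulus centre). Rounding is half away from zero.
#'
#' @param x_deg Coordinate in degrees (scalar or vector).
#' @param config A [display_config()].
#' @param axis `"x"` or `"y"`; selects which field extent bounds the check.
#' @return Integer pixel offsets.
#' @export
deg_to_px <- function(x_deg, config = display_config(), axis = c("x", "y")) {
  axis <- match.arg(axis)
  half <- if (axis == "x") config$field_width_deg / 2 else config$field_height_deg / 2
  if (any(abs(x_deg) > half + 1e-12)) {
    stop("coordinate ", paste(x_deg[abs(x_deg) > half], collapse = ", "),
         " deg lies outside the simulated field (half extent ", half, " deg)")
  }
  as.integer(round_half_away(x_deg * config$pixels_per_degree))
}

#' Inverse of [deg_to_px()]
#' @param px Integer pixel offsets from the origin.
#' @param config A [display_config()].
#' @return Degrees.
#' @export
px_to_deg <- function(px, config = display_config()) px / config$pixels_per_degree

arcsec_to_deg <- function(a) a / 3600

#' Vernier geometry
#'
#' Two abutting vertical segments, each half the total length; the lower
#' segment is displaced horizontally by `offset_deg` in `offset_direction`.
#'
#' @param eccentricity_deg Retinal eccentricity (metadata only).
#' @param length_deg Total vernier length.
#' @param width_arcsec Bar width in arcseconds.
#' @param offset_deg Horizontal offset of the lower segment.
#' @param offset_direction `"left"` or `"right"`.
#' @return An object of class `vernier_spec`.
#' @export
vernier_spec <- function(eccentricity_deg = 10.5, length_deg = 1.8,
                         width_arcsec = 210, offset_deg = 0.2,
                         offset_direction = c("right", "left")) {
  offset_direction <- match.arg(offset_direction)
  stopifnot(length_deg > 0, width_arcsec > 0, offset_deg >= 0)
  structure(list(
    eccentricity_deg = eccentricity_deg,
    length_deg = length_deg,
    width_arcsec = width_arcsec,
    width_deg = arcsec_to_deg(width_arcsec),
    offset_deg = offset_deg,
    offset_direction = offset_direction
  ), class = "vernier_spec")
}

#' Flanker geometry
#'
#' Three vertical lines per side, the nearest at `spacing_deg` from the
#' vernier column, all the same width as the vernier. Gapped flankers carry
#' two gaps of `gap_height_deg`, leaving three collinear segments; the middle
#' segment spans the vernier's vertical extent.
#'
#' @param n_per_side Lines per side.
#' @param spacing_deg Column spacing in degrees.
#' @param height_deg Total line height (1.8 for equal-length, 8.5 for long).
#' @param gapped Logical; if `TRUE`, two gaps split each line in three.
#' @param gap_height_deg Gap height in degrees.
#' @param middle_segment_height_deg Height of the middle (vernier-spanning)
#'   segment of a gapped line.
#' @return An object of class `flanker_spec`.
#' @export
flanker_spec <- function(n_per_side = 3, spacing_deg = 0.4, height_deg = 8.5,
                         gapped = FALSE, gap_height_deg = 1.25,
                         middle_segment_height_deg = 1.8) {
  stopifnot(n_per_side >= 1, spacing_deg > 0, height_deg > 0)
  if (gapped &&
      middle_segment_height_deg + 2 * gap_height_deg >= height_deg) {
    stop("gapped flanker: middle segment plus gaps exceed the line height")
  }
  structure(list(
    n_per_side = n_per_side, spacing_deg = spacing_deg,
    height_deg = height_deg, gapped = gapped,
    gap_height_deg = gap_height_deg,
    middle_segment_height_deg = middle_segment_height_deg
  ), class = "flanker_spec")
}

#' Pacman inducer geometry
#'
#' Four filled disks (left/right side times upper/lower gap row), each with a
#' horizontal rectangular cutout running from the centre to the perimeter.
#' The cutout height equals the flanker gap height and the disks are centred
#' vertically on the two gap rows.
#'
#' @param radius_deg Disk radius.
#' @param horizontal_distance_deg Centre-to-vernier-column distance.
#' @param mouth_direction `"inward"` (cutout faces the vernier) or
#'   `"outward"`.
#' @param mouth_height_deg Cutout height (defaults to the gap height).
#' @return An object of class `pacman_spec`.
#' @export
pacman_spec <- function(radius_deg = 1.125, horizontal_distance_deg = 3.33,
                        mouth_direction = c("inward", "outward"),
                        mouth_height_deg = 1.25) {
  mouth_direction <- match.arg(mouth_direction)
  stopifnot(radius_deg > 0, horizontal_distance_deg > 0,
            mouth_height_deg > 0, mouth_height_deg < 2 * radius_deg)
  structure(list(
    radius_deg = radius_deg,
    horizontal_distance_deg = horizontal_distance_deg,
    mouth_direction = mouth_direction,
    mouth_height_deg = mouth_height_deg
  ), class = "pacman_spec")
}

#' Build the declarative spec for a named condition
#'
#' @param condition One of [condition_names()].
#' @param offset_direction `"right"` or `"left"` vernier offset.
#' @return An object of class `stimulus_spec` with fields `condition`,
#'   `vernier`, `flankers` (or `NULL`) and `pacmen` (or `NULL`).
#' @examples
#' make_condition_spec("LONG", "right")
#' @export
make_condition_spec <- function(condition, offset_direction = c("right", "left")) {
  offset_direction <- match.arg(offset_direction)
  if (!condition %in% condition_names()) {
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(condition_names(), collapse = ", "))
  }
  vr <- vernier_spec(offset_direction = offset_direction)
  fl <- switch(condition,
    VERNIER_ONLY   = NULL,
    EQUAL_FLANKERS = flanker_spec(height_deg = vr$length_deg),
    LONG           = flanker_spec(),
    LONG_INWARD    = flanker_spec(),
    LONG_OUTWARD   = flanker_spec(),
    GAPPED         = flanker_spec(gapped = TRUE),
    GAPPED_INWARD  = flanker_spec(gapped = TRUE),
    GAPPED_OUTWARD = flanker_spec(gapped = TRUE)
  )
  pm <- switch(condition,
    GAPPED_INWARD  = pacman_spec(mouth_direction = "inward"),
    LONG_INWARD    = pacman_spec(mouth_direction = "inward"),
    GAPPED_OUTWARD = pacman_spec(mouth_direction = "outward"),
    LONG_OUTWARD   = pacman_spec(mouth_direction = "outward"),
    NULL
  )
  structure(list(condition = condition, vernier = vr,
                 flankers = fl, pacmen = pm),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec>", x$condition, "offset", x$vernier$offset_direction, "\n")
  if (!is.null(x$flankers)) {
    cat("  flankers: height", x$flankers$height_deg, "deg,",
        if (x$flankers$gapped) "gapped" else "continuous", "\n")
  }
  if (!is.null(x$pacmen)) {
    cat("  pacmen: 4x", x$pacmen$mouth_direction, "at",
        x$pacmen$horizontal_distance_deg, "deg\n")
  }
  invisible(x)
}

## ---- rasterization ---------------------------------------------------------

# Continuous vertical intervals [y1, y2) map to the half-open pixel-row range
# round(y1*ppd) .. round(y2*ppd)-1 so that abutting intervals tile without
# overlap (the vernier halves share no row). Columns of a thin bar span the
# half-open range round((x-w/2)*ppd) .. round((x+w/2)*ppd)-1 measured from
# the inner (centre-facing) edge, falling back to that edge column for
# sub-pixel widths: a sub-pixel bar snaps toward the stimulus axis, which
# keeps the background gap between the offset vernier segment and the
# nearest flanker intact at coarse resolutions and is exactly
# mirror-symmetric about x = 0 (negative x uses the mirrored positive rule).

rows_for_interval <- function(y1, y2, ppd) {
  a <- round_half_away(y1 * ppd)
  b <- round_half_away(y2 * ppd) - 1
  if (b < a) return(integer(0))
  seq.int(a, b)
}

cols_for_bar <- function(x, width, ppd) {
  if (x < 0) return(rev(-cols_for_bar(-x, width, ppd)))
  a <- round_half_away((x - width / 2) * ppd)
  b <- round_half_away((x + width / 2) * ppd) - 1
  seq.int(a, max(a, b))
}

#' Create a blank luminance image for a display configuration
#' @param config A [display_config()].
#' @return A `luminance_image`: list with `grid` (matrix of luminance
#'   fractions, rows = y increasing downward), `ppd`, `row0`/`col0` (matrix
#'   indices of the degree origin) and `background`.
#' @export
blank_image <- function(config = display_config()) {
  ppd <- config$pixels_per_degree
  rmin <- as.integer(round_half_away(-config$field_height_deg / 2 * ppd))
  rmax <- as.integer(round_half_away(config$field_height_deg / 2 * ppd))
  cmin <- as.integer(round_half_away(-config$field_width_deg / 2 * ppd))
  cmax <- as.integer(round_half_away(config$field_width_deg / 2 * ppd))
  grid <- matrix(config$background_luminance,
                 nrow = rmax - rmin + 1L, ncol = cmax - cmin + 1L)
  structure(list(grid = grid, ppd = ppd,
                 row0 = 1L - rmin, col0 = 1L - cmin,
                 background = config$background_luminance),
            class = "luminance_image")
}

#' @export
print.luminance_image <- function(x, ...) {
  cat("<luminance_image>", nrow(x$grid), "x", ncol(x$grid),
      "px at", x$ppd, "px/deg;",
      sum(x$grid < x$background), "non-background px\n")
  invisible(x)
}

# set pixels, erroring if any index leaves the field
img_set <- function(img, rows, cols, value, element = "element") {
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  ri <- rows + img$row0
  ci <- cols + img$col0
  if (min(ri) < 1L || max(ri) > nrow(img$grid) ||
      min(ci) < 1L || max(ci) > ncol(img$grid)) {
    stop("element '", element, "' exceeds the simulated field")
  }
  img$grid[ri, ci] <- value
  img
}

draw_vline <- function(img, x, y1, y2, width, lum, element) {
  img_set(img, rows_for_interval(y1, y2, img$ppd),
          cols_for_bar(x, width, img$ppd), lum, element)
}

draw_pacman <- function(img, cx, cy, pm, lum) {
  ppd <- img$ppd
  r <- pm$radius_deg
  rows <- rows_for_interval(cy - r, cy + r + 1 / ppd, ppd)
  cols <- seq.int(round_half_away((cx - r) * ppd), round_half_away((cx + r) * ppd))
  ri <- rows + img$row0
  ci <- cols + img$col0
  if (min(ri) < 1L || max(ri) > nrow(img$grid) ||
      min(ci) < 1L || max(ci) > ncol(img$grid)) {
    stop("element 'pacman' exceeds the simulated field")
  }
  y <- rows / ppd
  x <- cols / ppd
  inside <- outer(y - cy, x - cx, function(dy, dx) dy^2 + dx^2 <= r^2)
  # cutout: horizontal strip from the centre to the perimeter
  mouth_rows <- rows_for_interval(cy - pm$mouth_height_deg / 2,
                                  cy + pm$mouth_height_deg / 2, ppd)
  toward_vernier <- (pm$mouth_direction == "inward") == (cx > 0)
  mouth_cols <- if (toward_vernier) {
    seq.int(round_half_away((cx - r) * ppd), round_half_away(cx * ppd))
  } else {
    seq.int(round_half_away(cx * ppd), round_half_away((cx + r) * ppd))
  }
  inside[rows %in% mouth_rows, cols %in% mouth_cols] <- FALSE
  block <- img$grid[ri, ci]
  block[inside] <- lum
  img$grid[ri, ci] <- block
  img
}

#' Rasterize a stimulus specification
#'
#' Background at `background_luminance`, all elements at `element_luminance`.
#' Deterministic for a fixed configuration. The vernier upper segment sits on
#' the centre column; the lower segment is displaced by the offset.
#'
#' @param spec A `stimulus_spec` from [make_condition_spec()].
#' @param config A [display_config()].
#' @return A `luminance_image`.
#' @export
render <- function(spec, config = display_config()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  img <- blank_image(config)
  lum <- config$element_luminance
  vr <- spec$vernier
  sgn <- if (vr$offset_direction == "right") 1 else -1
  half <- vr$length_deg / 2
  img <- draw_vline(img, 0, -half, 0, vr$width_deg, lum, "vernier upper")
  img <- draw_vline(img, sgn * vr$offset_deg, 0, half, vr$width_deg, lum,
                    "vernier lower")
  fl <- spec$flankers
  if (!is.null(fl)) {
    hh <- fl$height_deg / 2
    mid <- fl$middle_segment_height_deg / 2
    gap <- fl$gap_height_deg
    for (k in seq_len(fl$n_per_side)) {
      for (s in c(-1, 1)) {
        x <- s * k * fl$spacing_deg
        nm <- sprintf("flanker %+d", as.integer(s * k))
        if (fl$gapped) {
          img <- draw_vline(img, x, -hh, -(mid + gap), vr$width_deg, lum, nm)
          img <- draw_vline(img, x, -mid, mid, vr$width_deg, lum, nm)
          img <- draw_vline(img, x, mid + gap, hh, vr$width_deg, lum, nm)
        } else {
          img <- draw_vline(img, x, -hh, hh, vr$width_deg, lum, nm)
        }
      }
    }
  }
  pm <- spec$pacmen
  if (!is.null(pm)) {
    mid <- if (!is.null(fl)) fl$middle_segment_height_deg / 2 else
      vr$length_deg / 2
    gap_centre <- mid + (if (!is.null(fl)) fl$gap_height_deg else
      pm$mouth_height_deg) / 2
    for (sx in c(-1, 1)) {
      for (sy in c(-1, 1)) {
        img <- draw_pacman(img, sx * pm$horizontal_distance_deg,
                           sy * gap_centre, pm, lum)
      }
    }
  }
  img
}

#' Mirror an image about the vertical axis through the stimulus centre
#' @param img A `luminance_image`.
#' @return The horizontally mirrored `luminance_image`.
#' @export
mirror_image <- function(img) {
  img$grid <- img$grid[, rev(seq_len(ncol(img$grid))), drop = FALSE]
  img$col0 <- ncol(img$grid) + 1L - img$col0
  img
}

#' Count dark connected components
#'
#' 4-connected flood fill over pixels strictly darker than the background.
#' Serves as the structural oracle for rendered stimuli (e.g. the gapped
#' configuration with inward Pacmans has 24 components: 6 lines x 3
#' segments + 2 vernier segments + 4 Pacmans).
#'
#' @param img A `luminance_image`.
#' @return List with `count` and integer `labels` matrix (0 = background).
#' @export
count_components <- function(img) {
  dark <- img$grid < img$background
  nr <- nrow(dark); nc <- ncol(dark)
  labels <- matrix(0L, nr, nc)
  count <- 0L
  idx <- which(dark)
  queue <- integer(length(idx))
  for (start in idx) {
    if (labels[start] != 0L) next
    count <- count + 1L
    labels[start] <- count
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (cc > 1L) p - nr, if (cc < nc) p + nr)) {
        if (dark[q] && labels[q] == 0L) {
          labels[q] <- count
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  list(count = count, labels = labels)
}

#' Write an image as a plain-text PGM (portable graymap)
#'
#' PGM is used instead of PNG so that exports stay plain text and
#' dependency-free; any standard image viewer or converter reads it.
#'
#' @param img A `luminance_image`.
#' @param path Output file path.
#' @param maxval Grey levels (default 255, 8-bit).
#' @return `path`, invisibly.
#' @export
write_image_pgm <- function(img, path, maxval = 255L) {
  g <- round(pmin(pmax(img$grid, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), as.character(maxval)), con)
  apply(g, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Serialize a stimulus spec (plus display config) to JSON
#' @param spec A `stimulus_spec`.
#' @param config Optional [display_config()] stored alongside.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spec_json <- function(spec, path, config = NULL) {
  payload <- list(condition = spec$condition,
                  offset_direction = spec$vernier$offset_direction)
  if (!is.null(config)) payload$display <- unclass(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a stimulus spec written by [write_spec_json()]
#' @param path JSON file.
#' @return List with `spec` (a `stimulus_spec`) and `config` (a
#'   `display_config` or `NULL`).
#' @export
read_spec_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- if (!is.null(payload$display)) do.call(display_config, payload$display)
  list(spec = make_condition_spec(payload$condition, payload$offset_direction),
       config = cfg)
}
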