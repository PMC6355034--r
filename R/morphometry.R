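#' Feret (caliper) diameters of a point set
#'
#' Maximum and minimum caliper diameters of the convex hull, by rotating
#' calipers: the maximum Feret diameter is the largest pairwise distance
#' between hull vertices; the minimum Feret diameter is the smallest
#' width over all hull-edge directions (for a convex polygon the minimum
#' width is always attained perpendicular to an edge). Pure geometry on
#' point coordinates — no pixel-width correction is applied here.
#'
#' @param points A 2-column matrix (or data frame with `x`, `y`) of
#'   point coordinates.
#' @return A one-row tibble with `feret` and `min_feret`.
#' @examples
#' feret_diameters(cbind(c(0, 4, 4, 0), c(0, 0, 3, 3)))  # 5 x 3 box: 5, 3
#' @export
feret_diameters <- function(points) {
  p <- as_xy(points)
  p <- unique(p)
  if (nrow(p) == 1) return(tibble(feret = 0, min_feret = 0))
  h <- p[grDevices::chull(p), , drop = FALSE]
  nh <- nrow(h)
  dmax <- 0
  for (i in seq_len(nh - 1)) {
    d2 <- (h[(i + 1):nh, 1] - h[i, 1])^2 + (h[(i + 1):nh, 2] - h[i, 2])^2
    dmax <- max(dmax, d2)
  }
  feret <- sqrt(dmax)
  if (nh == 2) {
    return(tibble(feret = feret, min_feret = 0))
  }
  widths <- vapply(seq_len(nh), function(i) {
    j <- if (i == nh) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- h %*% nrm
    max(proj) - min(proj)
  }, numeric(1))
  tibble(feret = feret, min_feret = min(widths))
}

# Perimeter of an 8-connected boundary chain: axial steps weigh 1,
# diagonal steps sqrt(2) (crack-following correction), closed loop.
contour_perimeter <- function(contour) {
  m <- as.matrix(contour)
  if (nrow(m) < 2) return(0)
  d <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE]) - m
  sum(sqrt(rowSums(d^2)))
}

#' Morphometric descriptors of one segmented cell
#'
#' Computes the head-shape panel on one blob: mean gray value (0-255, on
#' the original image), area (um^2, pixel count), perimeter (um, boundary
#' chain length with sqrt(2)-weighted diagonal steps), length and width
#' (um, maximum and minimum Feret diameters of the convex hull of the
#' boundary pixels, each corrected by +0.5 px for the finite pixel width),
#' and the derived ratios: ellipticity L/W, roughness 4*pi*A/P^2,
#' elongation (L-W)/(L+W), regularity pi*L*W/(4*A). Blobs touching the
#' image border are flagged as unreliable but still reported.
#'
#' @param blob One row of a [segment_frame()] result obtained with
#'   `keep_shapes = TRUE`.
#' @param image The grayscale image matrix the blob came from.
#' @param settings An [analysis_settings()] object (`um_per_px`).
#' @return A one-row tibble.
#' @export
measure_cell <- function(blob, image, settings) {
  stopifnot(nrow(blob) == 1, !is.null(blob$pixels), !is.null(blob$contour))
  um <- settings$um_per_px
  pix <- blob$pixels[[1]]
  ctr <- blob$contour[[1]]
  gray <- image
  if (max(gray) <= 1) gray <- gray * 255
  mean_gray <- mean(gray[cbind(pix[, 1], pix[, 2])])
  area <- nrow(pix) * um^2
  perim <- contour_perimeter(ctr) * um
  fer <- feret_diameters(ctr)
  # +0.5 px: calipers on boundary-pixel centres sit about a quarter pixel
  # inside the true outline on each side
  len <- (fer$feret + 0.5) * um
  wid <- (fer$min_feret + 0.5) * um
  blob_id <- blob$blob
  blob_x <- blob$x
  blob_y <- blob$y
  blob_border <- blob$on_border
  tibble(blob = blob_id, x = blob_x, y = blob_y,
         mean_gray = mean_gray, area = area, perimeter = perim,
         length = len, width = wid,
         ellipticity = len / wid,
         roughness = 4 * pi * area / perim^2,
         elongation = (len - wid) / (len + wid),
         regularity = pi * len * wid / (4 * area),
         on_border = blob_border)
}

#' Head morphometry of every cell in a still image
#'
#' Segments the image ([segment_frame()] with the size window of
#' `settings`), then measures every retained blob with [measure_cell()].
#' The semi-automated exclusion step is the `exclude` argument: blob ids
#' listed there (e.g. debris or overlapping heads spotted on inspection)
#' are dropped from the report.
#'
#' @param image A grayscale matrix, an RGB array (luminance is used), or a
#'   path readable by [read_image()].
#' @param settings An [analysis_settings()] object.
#' @param exclude Integer blob ids to omit.
#' @return A tibble with one row per measured cell.
#' @examples
#' img <- matrix(0, 80, 80); img[20:40, 30:44] <- 220
#' analyze_morphometry(img, analysis_settings(max_cell_size = 1000))
#' @export
analyze_morphometry <- function(image, settings, exclude = integer()) {
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) == 3) image <- as_gray(image)
  blobs <- segment_frame(image, settings, keep_shapes = TRUE)
  blobs <- blobs[!blobs$blob %in% exclude, , drop = FALSE]
  if (nrow(blobs) == 0) {
    return(tibble(blob = integer(), x = numeric(), y = numeric(),
                  mean_gray = numeric(), area = numeric(),
                  perimeter = numeric(), length = numeric(),
                  width = numeric(), ellipticity = numeric(),
                  roughness = numeric(), elongation = numeric(),
                  regularity = numeric(), on_border = logical()))
  }
  purrr::map_dfr(seq_len(nrow(blobs)), function(i) {
    measure_cell(blobs[i, ], image, settings)
  })
}
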