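#' Membrane-integrity (live/dead) counts from a dual-stained image
#'
#' Implements the two-channel workflow for acridine-orange / propidium-
#' iodide type staining: the red and green channels are segmented
#' independently (Otsu threshold, 8-connected components, the same
#' cell-size window as tracking); green-channel blobs are counted as
#' viable (membrane-intact) and red-channel blobs as non-viable. A cell
#' visible in both channels — footprints overlapping by more than half of
#' the smaller blob — is counted once and assigned to the channel with the
#' higher mean intensity over the blob footprint. The blue channel is
#' ignored.
#'
#' @param image An RGB array (`width` x `height` x 3, values 0-255 or
#'   0-1) or a path readable by [read_image()]. Grayscale input is
#'   rejected.
#' @param settings An [analysis_settings()] object.
#' @return An object of class `casa_viability`: per-cell tibble via
#'   [generics::tidy()], counts and percentages via [generics::glance()].
#' @examples
#' img <- array(0, c(60, 60, 3))
#' img[10:16, 10:15, 2] <- 255   # one green cell
#' img[40:46, 40:45, 1] <- 255   # one red cell
#' glance(classify_viability(img, analysis_settings()))
#' @export
classify_viability <- function(image, settings) {
  stopifnot(inherits(settings, "casa_settings"))
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("viability analysis needs an RGB image (3 channels)")
  }
  red <- image[, , 1]
  green <- image[, , 2]
  if (max(image) <= 1) {
    red <- red * 255
    green <- green * 255
  }
  seg <- function(ch) segment_frame(ch, settings, keep_shapes = TRUE)
  gb <- seg(green)
  rb <- seg(red)

  lab_of <- function(blobs, dims) {
    lab <- matrix(0L, dims[1], dims[2])
    for (i in seq_len(nrow(blobs))) {
      lab[blobs$pixels[[i]]] <- blobs$blob[i]
    }
    lab
  }
  rlab <- lab_of(rb, dim(red))

  g_drop <- integer()
  r_drop <- integer()
  for (i in seq_len(nrow(gb))) {
    pix <- gb$pixels[[i]]
    hits <- rlab[pix]
    hits <- hits[hits > 0L]
    if (!length(hits)) next
    for (j in unique(hits)) {
      ov <- sum(hits == j)
      if (ov > 0.5 * min(nrow(pix), rb$area_px[rb$blob == j])) {
        # same physical cell in both channels: keep the brighter channel
        rpix <- rb$pixels[[which(rb$blob == j)]]
        g_int <- mean(green[pix])
        r_int <- mean(red[rpix])
        if (g_int >= r_int) r_drop <- c(r_drop, j) else g_drop <- c(g_drop, i)
      }
    }
  }
  gb <- gb[!seq_len(nrow(gb)) %in% unique(g_drop), , drop = FALSE]
  rb <- rb[!rb$blob %in% unique(r_drop), , drop = FALSE]

  cells <- dplyr::bind_rows(
    tibble(x = gb$x, y = gb$y, area_um2 = gb$area_um2, label = "viable"),
    tibble(x = rb$x, y = rb$y, area_um2 = rb$area_um2, label = "nonviable"))
  n_v <- nrow(gb)
  n_n <- nrow(rb)
  tot <- n_v + n_n
  structure(list(cells = cells, n_viable = n_v, n_nonviable = n_n,
                 pct_viable = if (tot > 0) 100 * n_v / tot else NA_real_,
                 pct_nonviable = if (tot > 0) 100 * n_n / tot else NA_real_),
            class = "casa_viability")
}

#' @export
print.casa_viability <- function(x, ...) {
  cat("<casa_viability>\n")
  cat(sprintf("  viable %d (%.1f%%)  non-viable %d (%.1f%%)\n",
              x$n_viable, x$pct_viable, x$n_nonviable, x$pct_nonviable))
  invisible(x)
}
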