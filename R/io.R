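#' Read and write track tables
#'
#' Tracks travel as CSV with columns `track_id`, `frame`, `x_px`, `y_px`
#' and optionally `responsive`; in memory the coordinate columns are named
#' `x` and `y`. Reading sorts rows by track and frame (with a warning if
#' the file was out of order), so write-then-read is the identity on
#' values.
#'
#' @param path CSV file path.
#' @return `read_tracks()`: a track tibble. `write_tracks()`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' tr <- simulate_population(simulation_params(n_cells = 2, n_frames = 5))
#' write_tracks(tr, f)
#' read_tracks(f)
#' @export
read_tracks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("track_id", "frame", "x_px", "y_px")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("track file %s is missing column(s): %s",
                  path, toString(missing)))
  }
  out <- tibble(track_id = df$track_id, frame = df$frame,
                x = df$x_px, y = df$y_px)
  if ("responsive" %in% names(df)) out$responsive <- as.logical(df$responsive)
  ord <- order(out$track_id, out$frame)
  if (is.unsorted(ord)) {
    warn(sprintf("rows of %s were out of order; sorted by track and frame",
                 path))
    out <- out[ord, ]
  }
  out
}

#' @param tracks A track tibble.
#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  out <- tibble(track_id = tracks$track_id, frame = tracks$frame,
                x_px = tracks$x, y_px = tracks$y)
  if ("responsive" %in% names(tracks)) out$responsive <- tracks$responsive
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

img_to_matrix <- function(img) {
  d <- dim(img)
  m <- img@.Data
  if (length(d) == 3) {
    if (EBImage::colorMode(img) == EBImage::Color) {
      return(m * 255)              # keep channels, scale to 0-255
    }
    m <- m[, , 1]
  }
  m * 255
}

#' Read image frames for analysis
#'
#' `read_frames()` loads a video as a list of grayscale matrices
#' (0-255, first index x, second y), from either a multi-frame TIFF stack
#' or a character vector / glob of single-frame image files (TIFF, PNG or
#' JPEG), sorted by name. `read_image()` loads one still image, keeping
#' RGB channels when present. `write_frames()` writes a list of frame
#' matrices as a multi-frame TIFF.
#'
#' @param path A file path, a glob pattern (with `*`), or a vector of
#'   file paths.
#' @return `read_frames()`: a list of matrices. `read_image()`: a matrix
#'   or a 3-channel array.
#' @export
read_frames <- function(path) {
  if (length(path) == 1 && grepl("[*?]", path)) {
    path <- sort(Sys.glob(path))
  }
  if (length(path) == 0 || !all(file.exists(path))) {
    abort(sprintf("cannot read video frames from: %s",
                  toString(path[!file.exists(path)])))
  }
  frames <- unlist(lapply(path, function(p) {
    img <- EBImage::readImage(p)
    if (EBImage::colorMode(img) == EBImage::Color) {
      img <- EBImage::channel(img, "luminance")
    }
    m <- img@.Data * 255
    if (length(dim(m)) == 2) return(list(m))
    lapply(seq_len(dim(m)[3]), function(k) m[, , k])
  }), recursive = FALSE)
  if (!length(frames)) abort(sprintf("no frames found in %s", path[1]))
  frames
}

#' @param frames A list of grayscale frame matrices (0-255).
#' @rdname read_frames
#' @export
write_frames <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) >= 1)
  arr <- array(unlist(frames) / 255,
               dim = c(dim(frames[[1]]), length(frames)))
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff")
  invisible(path)
}

#' @rdname read_frames
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image not found: %s", path))
  img_to_matrix(EBImage::readImage(path))
}

#' Luminance of an RGB array
#'
#' Rec. 601 luminance, `0.299 R + 0.587 G + 0.114 B`, as used when a
#' colour still is analysed with the grayscale pipeline.
#'
#' @param image A `width` x `height` x 3 array.
#' @return A matrix on the same intensity scale.
#' @export
as_gray <- function(image) {
  stopifnot(length(dim(image)) == 3)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}
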