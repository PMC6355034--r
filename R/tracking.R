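#' Detect cells in a single grayscale frame
#'
#' Foreground is separated from background with Otsu's threshold, connected
#' components are extracted with 8-connectivity, and components whose area
#' (in square microns) falls outside the `[min_cell_size, max_cell_size]`
#' window are discarded. Centroids are intensity-weighted and sub-pixel.
#'
#' Frames are matrices in image convention: first index x (column of the
#' image), second index y (row), origin top-left, pixel centres at integer
#' coordinates. Intensities may be 0-255 or 0-1.
#'
#' @param frame Numeric matrix.
#' @param settings An [analysis_settings()] object; `invert = TRUE` flips
#'   the image first so dark cells on a bright background segment equally.
#' @param keep_shapes If `TRUE`, attach list-columns `pixels` (n x 2 integer
#'   matrix of pixel coordinates) and `contour` (ordered boundary points)
#'   needed for morphometry.
#'
#' @return A tibble with one row per detected blob: `blob`, `x`, `y`
#'   (weighted centroid, px), `area_px`, `area_um2`, `on_border`, and the
#'   shape list-columns when requested. A blank frame yields zero rows.
#' @examples
#' fr <- matrix(0, 50, 50); fr[10:16, 10:15] <- 255
#' segment_frame(fr, analysis_settings())
#' @export
segment_frame <- function(frame, settings, keep_shapes = FALSE) {
  stopifnot(is.matrix(frame), inherits(settings, "casa_settings"))
  v <- frame
  if (max(v) <= 1) v <- v * 255
  if (settings$invert) v <- 255 - v
  empty <- tibble(blob = integer(), x = numeric(), y = numeric(),
                  area_px = integer(), area_um2 = numeric(),
                  on_border = logical())
  if (keep_shapes) {
    empty$pixels <- list()
    empty$contour <- list()
  }
  rng <- range(v)
  if (diff(rng) < 1e-10) return(empty)
  thr <- otsu_threshold(v)
  storage.mode(v) <- "double"
  cc <- cc_stats8(v, thr)
  k <- length(cc$area)
  if (k == 0L) return(empty)
  areas <- cc$area
  keep <- which(areas * settings$um_per_px^2 >= settings$min_cell_size &
                  areas * settings$um_per_px^2 <= settings$max_cell_size)
  if (!length(keep)) return(empty)
  out <- tibble(blob = seq_along(keep),
                x = cc$swx[keep] / cc$sw[keep],
                y = cc$swy[keep] / cc$sw[keep],
                area_px = as.integer(areas[keep]),
                area_um2 = areas[keep] * settings$um_per_px^2,
                on_border = cc$border[keep] > 0L)
  if (keep_shapes) {
    lab <- cc$labels
    remap <- integer(k)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    idx <- which(lab > 0L)
    l <- lab[idx]
    nr <- nrow(lab)
    pix <- cbind(x = (idx - 1L) %% nr + 1L, y = (idx - 1L) %/% nr + 1L)
    ord <- order(l)
    out$pixels <- split.data.frame(pix[ord, , drop = FALSE], l[ord])
    oc <- EBImage::ocontour(lab)
    out$contour <- lapply(oc, function(m) m + 1L)  # ocontour is 0-based
  }
  out
}

#' Otsu threshold of a grayscale image
#'
#' Classic Otsu threshold on a 256-bin histogram of the 0-255 intensity
#' range: the split maximising the between-class variance. Pixels
#' strictly above the returned value are foreground. Non-integer
#' intensities are binned by their integer part.
#'
#' @param v A numeric matrix with values in 0-255.
#' @return The threshold, a single number in \[0, 255).
#' @export
otsu_threshold <- function(v) {
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  n <- sum(counts)
  w <- counts / n
  lv <- 0:255
  omega <- cumsum(w)
  mu <- cumsum(w * lv)
  mu_t <- mu[256]
  k <- 1:255
  denom <- omega[k] * (1 - omega[k])
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  which.max(sigma_b2) - 1
}

# 8-connected component labels of a logical/numeric mask (internal).
label_components <- function(mask) {
  m <- mask * 1
  storage.mode(m) <- "double"
  cc_stats8(m, 0)$labels
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment between consecutive frames: all
#' blob pairs closer than the search radius `max_displacement / um_per_px`
#' pixels are considered, matched in ascending distance order (ties broken
#' by blob index), each blob used at most once. Unmatched blobs in the new
#' frame start new tracks; tracks with no match terminate — there is no
#' gap closing, a missed detection ends the track.
#'
#' @param detections A list of per-frame blob tibbles from
#'   [segment_frame()], in frame order.
#' @param settings An [analysis_settings()] object.
#' @param frames Optional vector of frame indices (defaults to 0-based list
#'   positions).
#' @return A track tibble (`track_id`, `frame`, `x`, `y`).
#' @examples
#' s <- analysis_settings()
#' det <- lapply(0:3, function(f) tibble::tibble(blob = 1, x = 10 + 2 * f,
#'                                               y = 10, area_px = 60L))
#' link_frames(det, s)
#' @export
link_frames <- function(detections, settings, frames = NULL) {
  stopifnot(is.list(detections), inherits(settings, "casa_settings"))
  if (length(detections) < 2) abort("need detections for at least 2 frames")
  if (is.null(frames)) frames <- seq_along(detections) - 1L
  stopifnot(length(frames) == length(detections))
  r <- settings$max_displacement / settings$um_per_px
  nT <- length(detections)
  out <- vector("list", nT)

  cur <- detections[[1]]
  cur_ids <- seq_len(nrow(cur))
  next_id <- nrow(cur) + 1L
  out[[1]] <- tibble(track_id = cur_ids, frame = frames[1],
                     x = cur$x, y = cur$y)
  for (t in 2:nT) {
    prev <- cur
    prev_ids <- cur_ids
    cur <- detections[[t]]
    np <- nrow(prev)
    nc <- nrow(cur)
    ids <- integer(nc)
    if (np > 0 && nc > 0) {
      dx <- outer(prev$x, cur$x, "-")
      dy <- outer(prev$y, cur$y, "-")
      d <- sqrt(dx * dx + dy * dy)
      cand <- which(d <= r)
      if (length(cand)) {
        pi_ <- (cand - 1L) %% np + 1L
        ci_ <- (cand - 1L) %/% np + 1L
        ord <- order(d[cand], pi_, ci_)
        used_p <- logical(np)
        used_c <- logical(nc)
        for (e in ord) {
          i <- pi_[e]; j <- ci_[e]
          if (!used_p[i] && !used_c[j]) {
            used_p[i] <- TRUE
            used_c[j] <- TRUE
            ids[j] <- prev_ids[i]
          }
        }
      }
    }
    new <- which(ids == 0L)
    if (length(new)) {
      ids[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    cur_ids <- ids
    out[[t]] <- if (nc > 0) {
      tibble(track_id = ids, frame = frames[t], x = cur$x, y = cur$y)
    } else {
      tibble(track_id = integer(), frame = integer(),
             x = numeric(), y = numeric())
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$track_id, .data$frame)
}

#' Drop tracks shorter than the minimum track length
#'
#' @param tracks A track tibble.
#' @param settings An [analysis_settings()] object; tracks with fewer than
#'   `min_track_length` points are removed. Rejected if `min_track_length`
#'   exceeds the number of frames spanned by the data.
#' @return The filtered track tibble, original order preserved.
#' @examples
#' tr <- simulate_population(simulation_params(n_cells = 3, n_frames = 20))
#' nrow(filter_tracks(tr, analysis_settings(min_track_length = 5)))
#' @export
filter_tracks <- function(tracks, settings) {
  stopifnot(inherits(settings, "casa_settings"))
  if (nrow(tracks) == 0) return(tracks)
  n_video <- diff(range(tracks$frame)) + 1L
  if (settings$min_track_length > n_video) {
    abort(sprintf("min_track_length (%d) exceeds video length (%d frames)",
                  settings$min_track_length, n_video))
  }
  dplyr::group_by(tracks, .data$track_id) |>
    dplyr::filter(dplyr::n() >= settings$min_track_length) |>
    dplyr::ungroup()
}

#' Detect and track cells across a frame stack
#'
#' Convenience wrapper: [segment_frame()] on every frame, [link_frames()],
#' then [filter_tracks()].
#'
#' @param frames A list of grayscale frame matrices (see [read_frames()]).
#' @param settings An [analysis_settings()] object.
#' @param frame_ids Optional frame indices (default 0-based positions).
#' @return A track tibble.
#' @export
track_video <- function(frames, settings, frame_ids = NULL) {
  det <- lapply(frames, segment_frame, settings = settings)
  filter_tracks(link_frames(det, settings, frames = frame_ids), settings)
}
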