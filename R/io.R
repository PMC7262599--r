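# TIFF stack I/O. Stacks are stored frame-major, channel-minor (page order
# t1c1, t1c2, ..., t2c1, ...) as 16-bit TIFF, with calibration and channel
# roles in a YAML sidecar (<stem>.yaml) so a written stack round-trips
# without guessing. Calibration is mandatory: positions are always reported
# in um, never silently in pixels.

sidecar_path <- function(path) sub("\\.ome\\.tiff?$|\\.tiff?$", ".yaml", path)

#' Write an image stack to TIFF with a YAML metadata sidecar
#'
#' Pixel values must be integer camera counts in \[0, 65535\]; they are
#' stored as 16-bit samples, so the array round-trips bit-exactly.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (any(stack$data < 0 | stack$data > 65535 |
          stack$data != round(stack$data)))
    stop("stack values must be integer counts in [0, 65535]", call. = FALSE)
  pages <- list()
  for (f in seq_len(d[1])) for (ci in seq_len(d[2]))
    pages[[length(pages) + 1L]] <- stack$data[f, ci, , ] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size,
                        frame_interval_min = stack$frame_interval,
                        channels = as.list(stack$channels),
                        n_frames = d[1], ny = d[3], nx = d[4]),
                   sidecar_path(path))
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] (or any frame-major,
#' channel-minor stack) back into a `image_stack`. Calibration comes from
#' the YAML sidecar when present; otherwise `pixel_size`, `frame_interval`
#' and `channels` must be supplied -- missing calibration is an error, the
#' package never reports silent pixel units.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval,channels overrides / required when no
#'   sidecar exists.
#' @return an `image_stack` with integer counts.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("not a readable TIFF: ", path, call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  pixel_size <- pixel_size %||% meta$pixel_size_um
  frame_interval <- frame_interval %||% meta$frame_interval_min
  channels <- channels %||% unlist(meta$channels)
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("missing calibration: supply pixel_size (um/px) and ",
         "frame_interval (min) or provide the YAML sidecar", call. = FALSE)
  if (is.null(channels)) stop("channel roles are required", call. = FALSE)
  nc <- length(channels)
  if (length(pages) %% nc != 0)
    stop("page count is not a multiple of the channel count", call. = FALSE)
  nt <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nt, nc, ny, nx))
  k <- 1L
  for (f in seq_len(nt)) for (ci in seq_len(nc)) {
    arr[f, ci, , ] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  image_stack(arr, channels = channels, pixel_size = pixel_size,
              frame_interval = frame_interval)
}

#' Write a data.frame as CSV with a units comment header
#'
#' Every output table declares its units: a single leading comment line
#' names the unit conventions (um, min, px) before the standard CSV header.
#'
#' @param df data.frame.
#' @param path output path.
#' @param units comment text describing the units.
#' @return `path`, invisibly.
#' @export
write_units_csv <- function(df, path,
                            units = "units: x/y/d in um, t in min, areas in px") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_units_csv()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_units_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
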