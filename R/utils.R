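# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulation seeds never leak
#' into user sessions.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

# FNV-1a over the serialized object; used for run manifests only.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Convert pixel (col,row) coordinates to micrometres
#'
#' Pixel centres sit on an integer grid; pixel (row = 1, col = 1) maps to
#' (x, y) = (0, 0) um. `x` runs along columns, `y` along rows.
#' @param px numeric vector of pixel coordinates (1-based).
#' @param pixel_size pixel size in um/px.
#' @return numeric vector in um.
#' @export
px_to_um <- function(px, pixel_size) (px - 1) * pixel_size

#' Convert micrometre coordinates to (fractional) pixel coordinates
#' @param um numeric vector in um.
#' @param pixel_size pixel size in um/px.
#' @return numeric vector of 1-based pixel coordinates.
#' @export
um_to_px <- function(um, pixel_size) um / pixel_size + 1
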