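#' Monochrome frames
#'
#' A frame is the engine's unit of imagery: a height-by-width matrix of
#' integer grey levels in \[0, 255\], stamped with an acquisition time
#' (seconds since deployment start) and a resolution tier. Trigger
#' evaluation images (TEIs) are always 320 x 240 (width x height); full
#' resolution frames come at one of the tiers named in the camera
#' configuration (`"L"`, `"M"`, `"H"`).
#'
#' Pixels are stored top-left row-major: row 1 is the top image row,
#' column 1 the left edge. Region-of-interest coordinates in the
#' configuration use a bottom-left origin and are converted on crop (see
#' [crop_roi()]).
#'
#' @param pixels numeric matrix of grey levels; values are rounded and
#'   clamped to \[0, 255\].
#' @param timestamp acquisition time in seconds since deployment start.
#' @param tier resolution tier label, `"tei"` or `"full"` (full frames may
#'   additionally carry the configured tier letter in `attr(f, "res")`).
#' @return an `octo_frame`: the pixel matrix with class and metadata
#'   attributes.
#' @examples
#' f <- new_frame(matrix(128, 240, 320))
#' frame_dims(f)
#' @export
new_frame <- function(pixels, timestamp = 0, tier = "tei") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop("`pixels` must be a matrix with at least one row and column")
  }
  pixels <- clamp255(pixels)
  structure(pixels,
            timestamp = as.numeric(timestamp),
            tier = tier,
            class = c("octo_frame", "matrix", "array"))
}

#' @rdname new_frame
#' @param f an `octo_frame`.
#' @export
is_frame <- function(f) inherits(f, "octo_frame")

#' @rdname new_frame
#' @return `frame_dims()` returns `c(width, height)` in pixels.
#' @export
frame_dims <- function(f) c(width = ncol(f), height = nrow(f))

# round + clamp to 8-bit range, keeping storage double (fast array maths)
clamp255 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

frame_timestamp <- function(f) attr(f, "timestamp") %||% 0

# internal constructor for pixels already rounded/clamped (hot path)
new_frame_raw <- function(pixels, timestamp = 0, tier = "tei") {
  structure(pixels,
            timestamp = as.numeric(timestamp),
            tier = tier,
            class = c("octo_frame", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_tei <- function(f) {
  if (nrow(f) != 240L || ncol(f) != 320L) {
    stop(sprintf("TEI frames must be 320x240 (width x height); got %dx%d",
                 ncol(f), nrow(f)))
  }
  invisible(f)
}

#' @export
print.octo_frame <- function(x, ...) {
  cat(sprintf("<octo_frame %dx%d px, tier=%s, t=%.3fs, grey %d..%d>\n",
              ncol(x), nrow(x), attr(x, "tier") %||% "?",
              frame_timestamp(x), min(x), max(x)))
  invisible(x)
}

#' Read and write frames as image files
#'
#' Frames round-trip through the still-image formats the camera
#' configuration offers: JPEG, PNG and 8-bit greyscale BMP. JPEG quality
#' and PNG compression come from the `image_quality` setting. Colour
#' images are collapsed to luminance on read (the trigger path is
#' monochrome).
#'
#' @param f an `octo_frame`.
#' @param path output file; the format is taken from `type`, not the
#'   extension.
#' @param type one of `"jpeg"`, `"png"`, `"bmp"` (case-insensitive).
#' @param quality JPEG quality 70-100, or PNG compression level 0-9;
#'   ignored for BMP.
#' @return `write_frame()` returns `path` invisibly; `read_frame()`
#'   returns an `octo_frame` with timestamp 0.
#' @export
write_frame <- function(f, path, type = "png", quality = NULL) {
  type <- tolower(type)
  img <- unclass(f) / 255
  switch(type,
    jpeg = jpeg::writeJPEG(img, target = path,
                           quality = (quality %||% 95) / 100),
    png  = png::writePNG(img, target = path),
    bmp  = write_bmp8(unclass(f), path),
    stop(sprintf("unsupported image type '%s' (allowed: jpeg, png, bmp)", type))
  )
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path, type = NULL) {
  type <- tolower(type %||% tools::file_ext(path))
  if (type == "jpg") type <- "jpeg"
  px <- switch(type,
    jpeg = jpeg::readJPEG(path),
    png  = png::readPNG(path),
    bmp  = read_bmp8(path) / 255,
    stop(sprintf("unsupported image type '%s'", type))
  )
  if (length(dim(px)) == 3L) { # colour: ITU-R BT.601 luminance
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  new_frame(px * 255, timestamp = 0,
            tier = if (ncol(px) == 320 && nrow(px) == 240) "tei" else "full")
}

# Minimal 8-bit greyscale BMP (BITMAPINFOHEADER + 256-entry grey palette).
# Rows are stored bottom-up and padded to 4-byte multiples, per the format.
write_bmp8 <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  row_bytes <- ((w + 3) %/% 4) * 4
  data_size <- row_bytes * h
  offset <- 14L + 40L + 256L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("BM"), con)
  u32(offset + data_size); u16(0); u16(0); u32(offset)       # file header
  u32(40); u32(w); u32(h); u16(1); u16(8)                    # info header
  u32(0); u32(data_size); u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))        # grey BGRA
  writeBin(pal, con)
  pad <- raw(row_bytes - w)
  for (r in h:1) {                                           # bottom-up
    writeBin(c(as.raw(px[r, ]), pad), con)
  }
  invisible(path)
}

read_bmp8 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * 256^(0:1))
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file")
  offset <- u32(11); w <- u32(19); h <- u32(23)
  if (u16(29) != 8L) stop("only 8-bit greyscale BMP supported")
  row_bytes <- ((w + 3) %/% 4) * 4
  px <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    start <- offset + (r - 1) * row_bytes
    px[h - r + 1, ] <- as.integer(raw[start + seq_len(w)])
  }
  px
}
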