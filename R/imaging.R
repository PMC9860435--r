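#' Gaussian low-pass filter
#'
#' Separable Gaussian convolution used to stabilise trigger-evaluation
#' images before background subtraction. The standard deviation follows
#' the usual imaging-toolkit convention for a kernel of side `k`,
#' `sigma = 0.3 * ((k - 1) / 2 - 1) + 0.8` (1.1 for the stock 5 x 5
#' kernel). Borders are handled by symmetric reflection; the result is
#' rounded back to integer grey levels.
#'
#' @param f an `octo_frame`.
#' @param kernel_side odd kernel side length (default 5).
#' @return a blurred `octo_frame` of the same size and metadata.
#' @export
gaussian_blur <- function(f, kernel_side = 5L) {
  if (kernel_side < 1 || kernel_side %% 2 == 0) {
    stop("`kernel_side` must be an odd integer >= 1")
  }
  if (kernel_side == 1L) return(f)
  sigma <- 0.3 * ((kernel_side - 1) / 2 - 1) + 0.8
  h <- (kernel_side - 1L) %/% 2L
  g <- exp(-(-h:h)^2 / (2 * sigma^2))
  g <- g / sum(g)
  px <- sep_convolve(unclass(f), g)
  new_frame(px, timestamp = frame_timestamp(f), tier = attr(f, "tier"))
}

# separable convolution with symmetric-reflect borders (edge included)
sep_convolve <- function(m, g) {
  h <- (length(g) - 1L) %/% 2L
  conv_rows <- function(m) {           # vertical pass
    n <- nrow(m)
    idx <- c(h:1, 1:n, n:(n - h + 1L)) # reflected row indices
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(g)) {
      out <- out + g[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' Crop a frame to the trigger region of interest
#'
#' The trigger ROI is given as `(left, bottom, width, height)` with a
#' bottom-left pixel origin (offsets counted in pixels from the frame's
#' bottom-left corner), as configured in `settings.cfg`. Internally frames
#' are stored top-left row-major, so row `H - bottom - height + 1` of the
#' stored matrix is the top of the crop.
#'
#' @param f an `octo_frame`.
#' @param roi integer quadruple `(left, bottom, width, height)`.
#' @return the `width` x `height` sub-frame, with the ROI offset recorded
#'   in `attr(, "offset")`.
#' @export
crop_roi <- function(f, roi) {
  stopifnot(length(roi) == 4)
  left <- roi[1]; bottom <- roi[2]; w <- roi[3]; h <- roi[4]
  H <- nrow(f); W <- ncol(f)
  if (left < 0 || bottom < 0 || w < 1 || h < 1 ||
      left + w > W || bottom + h > H) {
    stop(sprintf("ROI [%s] exceeds the %dx%d frame bounds",
                 paste(roi, collapse = ", "), W, H))
  }
  rows <- (H - bottom - h + 1L):(H - bottom)
  cols <- (left + 1L):(left + w)
  out <- new_frame_raw(unclass(f)[rows, cols, drop = FALSE],
                       timestamp = frame_timestamp(f), tier = attr(f, "tier"))
  attr(out, "offset") <- c(left = left, bottom = bottom)
  out
}

#' Foreground masks
#'
#' A binary grid marking pixels classified as changed relative to the
#' background model, aligned to the (possibly ROI-cropped) frame it was
#' computed over. `offset` records the crop origin `(left, bottom)` in the
#' parent frame.
#'
#' @param bits matrix of 0/1 (or logical) values.
#' @param offset integer pair `(left, bottom)` into the parent frame.
#' @return an `octo_mask`.
#' @export
new_mask <- function(bits, offset = c(0L, 0L)) {
  if (is.logical(bits)) bits <- bits + 0
  if (any(bits != 0 & bits != 1)) stop("mask must be binary")
  structure(bits, offset = offset, class = c("octo_mask", "matrix", "array"))
}

#' @export
print.octo_mask <- function(x, ...) {
  cat(sprintf("<octo_mask %dx%d px, %d foreground>\n",
              ncol(x), nrow(x), sum(x)))
  invisible(x)
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_mat <- function(m, dr, dc, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Morphological closing of a foreground mask
#'
#' Dilation followed by erosion with a square structuring element, used to
#' merge fragmented detections that are likely a single target before
#' connected-component evaluation. Outside the mask the plane is treated
#' as background for dilation and as foreground for erosion (the neutral
#' paddings), so the all-zero and all-one masks are fixed points and
#' closing is idempotent.
#'
#' @param m an `octo_mask` (or 0/1 matrix).
#' @param kernel_side side of the square element (default 3).
#' @return the closed `octo_mask`.
#' @export
morph_close <- function(m, kernel_side = 3L) {
  if (kernel_side < 1) stop("`kernel_side` must be >= 1")
  off <- attr(m, "offset") %||% c(0L, 0L)
  b <- unclass(m) + 0
  n_fg <- sum(b)
  if (n_fg == 0 || n_fg == length(b)) return(new_mask(b, offset = off))
  new_mask(erode_bin(dilate_bin(b, kernel_side), kernel_side), offset = off)
}

# square structuring elements are separable: 1-D pass over rows, then cols
dilate_bin <- function(b, k) {
  h_lo <- (k - 1L) %/% 2L
  h_hi <- k %/% 2L
  out <- b
  for (dr in setdiff(-h_lo:h_hi, 0L)) out <- pmax(out, shift_mat(b, dr, 0L, 0))
  b2 <- out
  for (dc in setdiff(-h_lo:h_hi, 0L)) out <- pmax(out, shift_mat(b2, 0L, dc, 0))
  out
}

erode_bin <- function(b, k) {
  h_lo <- (k - 1L) %/% 2L
  h_hi <- k %/% 2L
  out <- b
  for (dr in setdiff(-h_lo:h_hi, 0L)) out <- pmin(out, shift_mat(b, dr, 0L, 1))
  b2 <- out
  for (dc in setdiff(-h_lo:h_hi, 0L)) out <- pmin(out, shift_mat(b2, 0L, dc, 1))
  out
}

#' Connected components of a foreground mask
#'
#' Labels maximal 8-connected foreground regions and reports per-component
#' pixel counts and bounding boxes. Components are numbered 1..n in order
#' of their first pixel in column-major scan; the label image keeps 0 for
#' background.
#'
#' @param m an `octo_mask` (or 0/1 matrix).
#' @return an `octo_components` list: `labels` (integer matrix), `sizes`
#'   (integer vector), and `bboxes` (tibble with one row per component:
#'   `component`, `size`, `row_min`, `row_max`, `col_min`, `col_max`).
#' @export
connected_components <- function(m) {
  b <- unclass(m) != 0
  H <- nrow(b); W <- ncol(b)
  labels <- matrix(0L, H, W)
  fg <- which(b)
  sizes <- integer()
  if (length(fg)) {
    nbr_off <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
    nbr_dr <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)  # row change per offset
    lab <- 0L
    for (seed in fg) {
      if (labels[seed] != 0L) next
      lab <- lab + 1L
      labels[seed] <- lab
      frontier <- seed
      n_px <- 1L
      # breadth-first expansion, whole frontier at once
      while (length(frontier)) {
        rows <- ((frontier - 1L) %% H) + 1L
        cand <- rep(frontier, each = 8L) + nbr_off
        cand_r <- rep(rows, each = 8L) + nbr_dr
        ok <- cand >= 1L & cand <= H * W & cand_r >= 1L & cand_r <= H
        cand <- cand[ok]
        cand <- unique(cand[b[cand] & labels[cand] == 0L])
        labels[cand] <- lab
        n_px <- n_px + length(cand)
        frontier <- cand
      }
      sizes <- c(sizes, n_px)
    }
  }
  bboxes <- if (length(sizes)) {
    rr <- ((which(labels != 0L) - 1L) %% H) + 1L
    cc <- ((which(labels != 0L) - 1L) %/% H) + 1L
    ll <- labels[labels != 0L]
    tibble::tibble(
      component = seq_along(sizes),
      size = sizes,
      row_min = as.integer(tapply(rr, ll, min)),
      row_max = as.integer(tapply(rr, ll, max)),
      col_min = as.integer(tapply(cc, ll, min)),
      col_max = as.integer(tapply(cc, ll, max))
    )
  } else {
    tibble::tibble(component = integer(), size = integer(),
                   row_min = integer(), row_max = integer(),
                   col_min = integer(), col_max = integer())
  }
  structure(list(labels = labels, sizes = sizes, bboxes = bboxes),
            class = "octo_components")
}

#' @export
print.octo_components <- function(x, ...) {
  cat(sprintf("<octo_components: %d component(s), %d foreground px>\n",
              length(x$sizes), sum(x$sizes)))
  invisible(x)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with histogram clipping and bilinear
#' interpolation between tile mappings, applied to full-resolution
#' captures when `auto_contrast` is enabled. Each tile's 256-bin histogram
#' is clipped at `clip_limit` times the uniform bin height; the clipped
#' excess is redistributed evenly before the cumulative mapping is built.
#' Pixels between tile centres blend the four surrounding tile mappings.
#'
#' @param f an `octo_frame`.
#' @param clip_limit positive clip factor (default 2).
#' @param tiles integer pair `(rows, cols)` of the tile grid (default 8x8).
#' @return the equalized `octo_frame`.
#' @export
clahe <- function(f, clip_limit = 2, tiles = c(8L, 8L)) {
  if (clip_limit <= 0) stop("`clip_limit` must be > 0")
  tr <- tiles[1]; tc <- tiles[2]
  if (tr < 1 || tc < 1) stop("`tiles` must be >= (1, 1)")
  H <- nrow(f); W <- ncol(f)
  if (H < tr || W < tc) {
    stop(sprintf("frame %dx%d smaller than the %dx%d tile grid", W, H, tc, tr))
  }
  px <- unclass(f)
  row_brk <- round(seq(0, H, length.out = tr + 1))
  col_brk <- round(seq(0, W, length.out = tc + 1))
  luts <- array(0, c(tr, tc, 256L))
  centres_r <- numeric(tr); centres_c <- numeric(tc)
  for (i in seq_len(tr)) {
    rows <- (row_brk[i] + 1):row_brk[i + 1]
    centres_r[i] <- mean(rows)
    for (j in seq_len(tc)) {
      cols <- (col_brk[j] + 1):col_brk[j + 1]
      if (i == 1) centres_c[j] <- mean(cols)
      tile <- px[rows, cols]
      hist <- tabulate(tile + 1L, nbins = 256L)
      n <- length(tile)
      clip <- max(1, clip_limit * n / 256)
      excess <- sum(pmax(hist - clip, 0))
      hist <- pmin(hist, clip) + excess / 256
      luts[i, j, ] <- clamp255(cumsum(hist) * 255 / n)
    }
  }
  # bilinear blend of the four surrounding tile mappings
  ri <- findInterval(seq_len(H), centres_r)          # lower tile row (0..tr)
  r0 <- pmax(ri, 1L); r1 <- pmin(ri + 1L, tr)
  wr <- ifelse(r0 == r1, 0,
               (seq_len(H) - centres_r[r0]) / (centres_r[r1] - centres_r[r0]))
  wr <- pmin(pmax(wr, 0), 1)
  ci <- findInterval(seq_len(W), centres_c)
  c0 <- pmax(ci, 1L); c1 <- pmin(ci + 1L, tc)
  wc <- ifelse(c0 == c1, 0,
               (seq_len(W) - centres_c[c0]) / (centres_c[c1] - centres_c[c0]))
  wc <- pmin(pmax(wc, 0), 1)

  v <- as.integer(px) + 1L                            # 1..256 bin index
  R0 <- rep(r0, times = W); R1 <- rep(r1, times = W)
  C0 <- rep(c0, each = H); C1 <- rep(c1, each = H)
  WR <- rep(wr, times = W); WC <- rep(wc, each = H)
  out <- (1 - WR) * (1 - WC) * luts[cbind(R0, C0, v)] +
         (1 - WR) * WC       * luts[cbind(R0, C1, v)] +
         WR       * (1 - WC) * luts[cbind(R1, C0, v)] +
         WR       * WC       * luts[cbind(R1, C1, v)]
  new_frame(matrix(out, H, W),
            timestamp = frame_timestamp(f), tier = attr(f, "tier"))
}
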