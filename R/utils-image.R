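## Image-coordinate convention used throughout the cell module:
## (x, y) = (column, row), pixel centers at integer coordinates.

#' @noRd
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  r_dst <- seq_len(nr)[seq_len(nr) + dr >= 1L & seq_len(nr) + dr <= nr]
  c_dst <- seq_len(nc)[seq_len(nc) + dc >= 1L & seq_len(nc) + dc <= nc]
  out[r_dst, c_dst] <- m[r_dst + dr, c_dst + dc]
  out
}

#' Bilinear interpolation of an image at continuous coordinates
#' Coordinates are clamped to the image extent.
#' @noRd
bilinear_at <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * nr + y0
  v00 <- img[i00];      v10 <- img[i00 + nr]
  v01 <- img[i00 + 1];  v11 <- img[i00 + nr + 1]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Nearest-pixel membership of continuous points in one labelled cell
#' @noRd
in_cell <- function(mask, cell_id, x, y) {
  ## floor(x + 0.5), not round(): banker's rounding of *.5 coordinates
  ## would make membership depend on the parity of the crop offset
  r <- floor(y + 0.5); c <- floor(x + 0.5)
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  out <- logical(length(x))
  out[ok] <- mask[cbind(r[ok], c[ok])] == cell_id
  out
}

#' Moving-average smoothing with shrinking windows at the ends
#' @noRd
smooth_ma <- function(v, window) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  if (h < 1L || n < 3L) return(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Resample an open polyline to (approximately) unit arc-length spacing
#' @noRd
resample_polyline <- function(xy, spacing = 1) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  keep <- c(TRUE, seg > 1e-9)
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 2L) return(xy)
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  len <- s[length(s)]
  np <- max(2L, round(len / spacing) + 1L)
  t <- seq(0, len, length.out = np)
  cbind(x = approx(s, xy[, 1], t)$y, y = approx(s, xy[, 2], t)$y)
}

#' @noRd
polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

#' Euclidean distance transform of a logical matrix (to background)
#' @noRd
euclid_dt <- function(m) {
  d <- EBImage::distmap(matrix(as.numeric(m), nrow(m)))
  matrix(EBImage::imageData(d), nrow(m))
}

#' Bounding boxes of all labels in one pass over the mask
#' @noRd
all_bboxes <- function(mask, pad = 3L) {
  idx <- which(mask != 0L)
  if (!length(idx)) return(list())
  lab <- mask[idx]
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  f <- factor(lab)
  out <- setNames(vector("list", nlevels(f)), levels(f))
  rmin <- tapply(r, f, min); rmax <- tapply(r, f, max)
  cmin <- tapply(c, f, min); cmax <- tapply(c, f, max)
  for (l in levels(f)) {
    out[[l]] <- list(
      rows = max(1L, rmin[[l]] - pad):min(nrow(mask), rmax[[l]] + pad),
      cols = max(1L, cmin[[l]] - pad):min(ncol(mask), cmax[[l]] + pad)
    )
  }
  out
}

#' @noRd
cell_bbox <- function(mask, cell_id, pad = 3L) {
  idx <- which(mask == cell_id, arr.ind = TRUE)
  if (!nrow(idx)) stop("cell_id ", cell_id, " not present in mask")
  list(
    rows = max(1L, min(idx[, 1]) - pad):min(nrow(mask), max(idx[, 1]) + pad),
    cols = max(1L, min(idx[, 2]) - pad):min(ncol(mask), max(idx[, 2]) + pad),
    idx = idx
  )
}
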