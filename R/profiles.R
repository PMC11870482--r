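#' Axial fluorescence intensity profile of one cell
#'
#' At each of the n axis positions, the raw intensity I_i is the sum of
#' `width_px` samples taken along the local perpendicular to the axis
#' (bilinear interpolation, 1 px apart, restricted to samples whose nearest
#' pixel belongs to the cell). No background subtraction is applied; the
#' profile normalisation (see [normalize_profile()]) operates on raw sums.
#'
#' @param image Numeric fluorescence matrix.
#' @param mask Integer label matrix, congruent with `image`.
#' @param cell_id Cell label.
#' @param axis Axis matrix from [extract_cell_axis()].
#' @param width_px Odd number of perpendicular samples per position
#'   (default 5).
#' @return An object of class `cell_profile`: list with `cell_id`, `n`
#'   (profile length), `I` (raw intensities) and `I_norm` (`NULL` until
#'   [normalize_profile()] is applied).
#' @export
axis_profile <- function(image, mask, cell_id, axis, width_px = 5L) {
  stopifnot(all(dim(image) == dim(mask)))
  if (width_px %% 2L != 1L) stop("`width_px` must be odd")
  xy <- unclass(axis)
  n <- nrow(xy)
  if (n < 3L) stop("axis must have at least 3 positions")
  if (!all(in_cell(mask, cell_id, xy[, 1], xy[, 2])))
    stop("axis passes outside the cell mask")
  tang <- axis_tangents(xy)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)
  xs <- xy[, 1] + outer(-tang[, 2], offs)   # normal = (-ty, tx)
  ys <- xy[, 2] + outer(tang[, 1], offs)
  keep <- in_cell(mask, cell_id, as.vector(xs), as.vector(ys))
  vals <- bilinear_at(image, as.vector(xs), as.vector(ys))
  vals[!keep] <- 0
  I <- rowSums(matrix(vals, nrow = n))
  structure(list(cell_id = attr(axis, "cell_id") %||% cell_id,
                 n = n, I = I, I_norm = NULL),
            class = "cell_profile")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unit tangents along an axis polyline (central differences)
#' @noRd
axis_tangents <- function(xy) {
  n <- nrow(xy)
  dx <- c(xy[2L, 1] - xy[1L, 1], xy[-(1:2), 1] - xy[seq_len(n - 2L), 1],
          xy[n, 1] - xy[n - 1L, 1])
  dy <- c(xy[2L, 2] - xy[1L, 2], xy[-(1:2), 2] - xy[seq_len(n - 2L), 2],
          xy[n, 2] - xy[n - 1L, 2])
  nv <- sqrt(dx^2 + dy^2)
  nv[nv < 1e-12] <- 1
  cbind(dx / nv, dy / nv)
}

#' Normalise an axial profile to unit mean
#'
#' Applies the demograph normalisation `I_norm_i = I_i * n / sum(I)`, where
#' n is the profile length, so that every normalised profile has mean 1
#' (equivalently, sums to n) regardless of the cell's absolute brightness.
#'
#' @param profile A `cell_profile` from [axis_profile()], or a bare numeric
#'   vector of raw intensities.
#' @return The same type as the input, with the normalised intensities
#'   filled in.
#' @export
normalize_profile <- function(profile) {
  if (is.numeric(profile)) {
    s <- sum(profile)
    if (!is.finite(s) || s <= 0) stop("profile sum must be positive")
    return(profile * length(profile) / s)
  }
  stopifnot(inherits(profile, "cell_profile"))
  profile$I_norm <- normalize_profile(profile$I)
  profile
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("<cell_profile> cell %s, n = %d%s\n", x$cell_id, x$n,
              if (is.null(x$I_norm)) " (raw)" else " (normalized)"))
  invisible(x)
}

#' Build a demograph from per-cell axial profiles
#'
#' Stacks normalised axial profiles into a matrix whose rows are cells
#' sorted by ascending cell length and whose columns are a fixed number of
#' relative axial-coordinate bins in [0, 1]; each profile is linearly
#' resampled onto the common bins. The standard visual summary of septal
#' protein localisation across the cell cycle.
#'
#' @param profiles List of `cell_profile` objects (normalised; raw profiles
#'   are normalised on the fly).
#' @param lengths Numeric vector of cell lengths (same order as
#'   `profiles`) used for sorting; defaults to the profile lengths `n`.
#' @param n_bins Number of relative-coordinate bins (default 100).
#' @return An object of class `demograph`: list with `matrix` (cells x
#'   bins), `lengths` (sorted), `cell_ids`.
#' @export
build_demograph <- function(profiles, lengths = NULL, n_bins = 100L) {
  if (!length(profiles)) stop("no profiles to stack")
  profiles <- lapply(profiles, function(p)
    if (is.null(p$I_norm)) normalize_profile(p) else p)
  if (is.null(lengths))
    lengths <- vapply(profiles, function(p) as.numeric(p$n), numeric(1L))
  stopifnot(length(lengths) == length(profiles))
  ord <- order(lengths)
  bins <- seq(0, 1, length.out = n_bins)
  m <- t(vapply(profiles[ord], function(p)
    approx(seq(0, 1, length.out = p$n), p$I_norm, xout = bins)$y,
    numeric(n_bins)))
  dimnames(m) <- NULL
  structure(list(
    matrix = m,
    lengths = unname(lengths[ord]),
    cell_ids = unname(vapply(profiles[ord], function(p)
      as.character(p$cell_id), character(1L)))
  ), class = "demograph")
}

#' Plot a demograph
#'
#' @param x A `demograph`.
#' @param col Colour palette (default `hcl.colors(64, "viridis")`).
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot_demograph <- function(x, col = grDevices::hcl.colors(64, "viridis"),
                           ...) {
  stopifnot(inherits(x, "demograph"))
  graphics::image(
    x = seq(0, 1, length.out = ncol(x$matrix)),
    y = seq_len(nrow(x$matrix)),
    z = t(x$matrix), col = col,
    xlab = "relative position along cell axis",
    ylab = "cells (sorted by length)", ...
  )
  invisible(x)
}
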