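#' Midcell-minus-quarter intensity of one cell
#'
#' Measures the mean fluorescence in a perpendicular band of
#' `line_width_px` axis positions (default 3) centred at the axial midpoint
#' (the septum in dividing cells), and subtracts the same measurement taken
#' at the quarter position as a cytoplasmic background estimate. By default
#' the background is the average of the 25% and 75% axis positions
#' (symmetric); `quarter = "single"` uses only the 25% position.
#'
#' @inheritParams axis_profile
#' @param line_width_px Band thickness along the axis, in axis positions
#'   (default 3).
#' @param quarter `"both"` (mean of 25% and 75% positions, default) or
#'   `"single"` (25% only).
#' @return One-row tibble with `cell_id`, `midcell_raw`, `quarter_raw` and
#'   `value = midcell_raw - quarter_raw`.
#' @export
midcell_intensity <- function(image, mask, cell_id, axis, line_width_px = 3L,
                              quarter = c("both", "single")) {
  stopifnot(all(dim(image) == dim(mask)))
  quarter <- match.arg(quarter)
  xy <- unclass(axis)
  if (nrow(xy) < 8L) stop("axis too short for a midcell measurement (need >= 8 positions)")
  max_half <- attr(axis, "max_dt_px") %||% (min(dim(mask)) / 2)
  band <- function(frac) perp_band_mean(image, mask, cell_id, xy, frac,
                                        line_width_px, max_half)
  midcell_raw <- band(0.5)
  quarter_raw <- if (quarter == "both")
    mean(c(band(0.25), band(0.75)))
  else band(0.25)
  tibble(cell_id = attr(axis, "cell_id") %||% cell_id,
         midcell_raw = midcell_raw, quarter_raw = quarter_raw,
         value = midcell_raw - quarter_raw)
}

#' Raw midcell/quarter band means without the tibble wrapper
#' @noRd
midcell_values <- function(image, mask, cell_id, axis, line_width_px = 3L) {
  xy <- unclass(axis)
  max_half <- attr(axis, "max_dt_px") %||% (min(dim(mask)) / 2)
  m <- perp_band_mean(image, mask, cell_id, xy, 0.5, line_width_px, max_half)
  q <- mean(c(
    perp_band_mean(image, mask, cell_id, xy, 0.25, line_width_px, max_half),
    perp_band_mean(image, mask, cell_id, xy, 0.75, line_width_px, max_half)))
  list(midcell_raw = m, quarter_raw = q, value = m - q)
}

#' Mean intensity over a perpendicular band at a relative axis position
#' @noRd
perp_band_mean <- function(image, mask, cell_id, xy, frac, line_width_px,
                           max_half, step = 0.5) {
  n <- nrow(xy)
  i0 <- round(1 + (n - 1) * frac)
  half <- (line_width_px - 1) %/% 2
  rows <- unique(pmin(pmax(i0 + seq.int(-half, half), 1L), n))
  tang <- axis_tangents(xy)
  offs <- seq(-(max_half + 1), max_half + 1, by = step)
  xs <- xy[rows, 1] + outer(-tang[rows, 2], offs)
  ys <- xy[rows, 2] + outer(tang[rows, 1], offs)
  keep <- in_cell(mask, cell_id, as.vector(xs), as.vector(ys))
  if (!any(keep)) stop("midcell band lies entirely outside the cell mask")
  vals <- bilinear_at(image, as.vector(xs), as.vector(ys))
  mean(vals[keep])
}

#' Normalise midcell intensities to a per-replicate control median
#'
#' Divides every measurement by the median `value` of the control group
#' within the same biological replicate, yielding the "relative midcell
#' intensity". By construction the per-replicate median of the normalised
#' control values is 1.
#'
#' @param measurements Data frame with (at least) a group column, a
#'   replicate column and a value column.
#' @param control_group Label of the control group (e.g. the wild-type
#'   strain).
#' @param group_col,replicate_col,value_col Column names (defaults
#'   `"group"`, `"replicate"`, `"value"`).
#' @return The input tibble with an added `relative_value` column.
#' @export
normalize_by_control <- function(measurements, control_group,
                                 group_col = "group",
                                 replicate_col = "replicate",
                                 value_col = "value") {
  m <- as_tibble(measurements)
  for (col in c(group_col, replicate_col, value_col))
    if (!col %in% names(m)) stop("measurements lack column `", col, "`")
  if (!control_group %in% m[[group_col]])
    stop("control group '", control_group, "' absent from measurements")
  reps <- unique(m[[replicate_col]])
  med <- setNames(numeric(length(reps)), as.character(reps))
  for (r in as.character(reps)) {
    ctrl <- m[[value_col]][m[[replicate_col]] == r &
                             m[[group_col]] == control_group]
    if (!length(ctrl))
      stop("replicate '", r, "' contains no control ('", control_group,
           "') measurements")
    md <- median(ctrl)
    if (!is.finite(md) || md <= 0)
      stop("control median in replicate '", r, "' is not positive")
    med[r] <- md
  }
  m$relative_value <- unname(m[[value_col]] /
                               med[as.character(m[[replicate_col]])])
  m
}

#' Nonparametric two-group comparison of midcell intensities
#'
#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum with tie correction,
#' normal approximation) between two samples of (relative) midcell
#' intensities.
#'
#' @param x,y Numeric samples (each of length >= 3).
#' @return A list of class `mw_comparison` with `U` (statistic for `x`),
#'   `p_value`, `median_x`, `median_y`, `n_x`, `n_y`.
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("each sample needs at least 3 observations")
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                correct = TRUE)
  )
  structure(list(
    U = unname(ht$statistic),
    p_value = ht$p.value,
    median_x = median(x), median_y = median(y),
    n_x = length(x), n_y = length(y)
  ), class = "mw_comparison")
}

#' @export
print.mw_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, two-sided p = %.4g\n", x$U, x$p_value))
  cat(sprintf("  medians: %.4g (n=%d) vs %.4g (n=%d)\n",
              x$median_x, x$n_x, x$median_y, x$n_y))
  invisible(x)
}
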