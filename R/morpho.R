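#' Cell morphometrics from a label mask
#'
#' Length is the medial-axis arc length times the pixel size; width is the
#' average perpendicular extent along the axis: twice the Euclidean
#' distance-transform value (distance to the cell boundary) averaged over
#' the central half of the axis, so the tapering pole caps do not drag the
#' width of the cylindrical body down.
#'
#' @param mask Integer label matrix (0 = background).
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param cell_ids Labels to measure (default: all labels in the mask).
#' @return A tibble with one row per cell: `cell_id`, `length_um`,
#'   `width_um`, `excluded` (logical) and `reason` (why a cell was skipped,
#'   `NA` otherwise).
#' @export
cell_morphometrics <- function(mask, pixel_size, cell_ids = NULL) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  if (is.null(cell_ids)) cell_ids <- setdiff(sort(unique(as.vector(mask))), 0)
  if (!length(cell_ids)) stop("no cells in mask")
  rows <- lapply(cell_ids, function(id) {
    res <- tryCatch(measure_one_cell(mask, id, pixel_size),
                    septalink_cell_excluded = function(e)
                      tibble(cell_id = id, length_um = NA_real_,
                             width_um = NA_real_, excluded = TRUE,
                             reason = e$reason))
    res
  })
  dplyr::bind_rows(rows)
}

#' @noRd
measure_one_cell <- function(mask, id, pixel_size) {
  axis <- extract_cell_axis(mask, id)
  tibble(cell_id = id,
         length_um = attr(axis, "arc_length_px") * pixel_size,
         width_um = axis_mean_width_px(mask, id, axis) * pixel_size,
         excluded = FALSE, reason = NA_character_)
}

#' Mean perpendicular extent (px) along an axis: 2 x distance transform,
#' averaged over the central half of the axis (25%-75% of arc length) so
#' the tapering pole caps do not bias the width of the cylindrical body.
#' @noRd
axis_mean_width_px <- function(mask, id, axis) {
  dt <- attr(axis, "dt_crop")
  if (!is.null(dt)) {
    off <- attr(axis, "dt_offset")
    ox <- off[["x"]]; oy <- off[["y"]]
  } else {
    bb <- cell_bbox(mask, id)
    dt <- euclid_dt(mask[bb$rows, bb$cols] == id)
    ox <- bb$cols[1L]; oy <- bb$rows[1L]
  }
  n <- nrow(axis)
  mid <- seq.int(ceiling(n * 0.25), floor(n * 0.75))
  xs <- axis[mid, 1] - ox + 1
  ys <- axis[mid, 2] - oy + 1
  ## distmap measures to the nearest background pixel *center*, which lies
  ## on average half a pixel beyond the true boundary, so no half-pixel
  ## boundary correction is added.
  mean(2 * bilinear_at(dt, xs, ys))
}

#' Per-cell analysis of one image/mask pair
#'
#' Convenience driver running the whole single-cell pipeline on every label
#' of a mask: medial axis, raw and normalised axial profile, morphometrics
#' and the midcell-minus-quarter statistic. Cells excluded by
#' [extract_cell_axis()] (border-touching, too small, not elongated) are
#' counted and reported with their reason, not silently dropped.
#'
#' @param image Numeric fluorescence matrix.
#' @param mask Integer label matrix, congruent with `image`.
#' @param pixel_size Micrometres per pixel (default 0.065).
#' @param profile_width_px Perpendicular samples per profile position
#'   (default 5).
#' @param line_width_px Midcell band thickness in axis positions
#'   (default 3).
#' @return A list with `cells` (tibble: `cell_id`, `n`, `length_um`,
#'   `width_um`, `midcell_raw`, `quarter_raw`, `value`), `profiles` (named
#'   list of normalised `cell_profile`s) and `excluded` (tibble of skipped
#'   cells with reasons).
#' @export
analyze_cells <- function(image, mask, pixel_size = 0.065,
                          profile_width_px = 5L, line_width_px = 3L) {
  ids <- setdiff(sort(unique(as.vector(mask))), 0)
  if (!length(ids)) stop("no cells in mask")
  bbs <- all_bboxes(mask, pad = 4L)
  rows <- vector("list", length(ids))
  profiles <- list()
  excl_id <- integer(); excl_reason <- character()
  border_ids <- border_labels(mask)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% border_ids) {
      excl_id <- c(excl_id, id)
      excl_reason <- c(excl_reason, "touches image border")
      next
    }
    bb <- bbs[[as.character(id)]]
    sub_mask <- mask[bb$rows, bb$cols]
    sub_img <- image[bb$rows, bb$cols]
    res <- tryCatch({
      axis <- extract_cell_axis(sub_mask, id)
      prof <- normalize_profile(
        axis_profile(sub_img, sub_mask, id, axis, width_px = profile_width_px))
      mid <- midcell_values(sub_img, sub_mask, id, axis,
                            line_width_px = line_width_px)
      list(row = list(
        cell_id = id, n = prof$n,
        length_um = attr(axis, "arc_length_px") * pixel_size,
        width_um = axis_mean_width_px(sub_mask, id, axis) * pixel_size,
        midcell_raw = mid$midcell_raw, quarter_raw = mid$quarter_raw,
        value = mid$value), profile = prof)
    }, septalink_cell_excluded = function(e) list(reason = e$reason))
    if (!is.null(res$row)) {
      rows[[i]] <- res$row
      profiles[[as.character(id)]] <- res$profile
    } else {
      excl_id <- c(excl_id, id)
      excl_reason <- c(excl_reason, res$reason)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  cells <- if (length(rows))
    as_tibble(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
  else
    tibble(cell_id = integer(), n = integer(), length_um = numeric(),
           width_um = numeric(), midcell_raw = numeric(),
           quarter_raw = numeric(), value = numeric())
  list(cells = cells, profiles = profiles,
       excluded = tibble(cell_id = excl_id, reason = excl_reason))
}

#' Labels present on the outermost pixel ring of the mask
#' @noRd
border_labels <- function(mask) {
  unique(c(mask[1L, ], mask[nrow(mask), ], mask[, 1L], mask[, ncol(mask)]))
}
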