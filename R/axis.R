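#' Morphological skeleton of a binary mask (anchored Zhang-Suen thinning)
#'
#' Iterative homotopic thinning reducing a connected foreground region to a
#' thin, 8-connected skeleton. Optionally, `anchor` pixels are never
#' removed: anchoring at the local maxima of the Euclidean distance
#' transform turns plain thinning into a medial-axis transform and prevents
#' the well-known erosion of blunt line ends (without anchors, a short
#' diagonal rod can collapse to a few pixels before its ridge forms).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param anchor Optional logical matrix of protected pixels.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask, anchor = NULL) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  if (is.null(anchor)) anchor <- matrix(FALSE, nrow(m), ncol(m))
  stopifnot(all(dim(anchor) == dim(m)))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(m, -1L, 0L);  p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L);   p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L);   p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L);  p9 <- shift_mat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- if (phase == 1L)
        p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      else
        p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      del <- m == 1L & !anchor & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Longest geodesic path through a skeleton (branch pruning)
#'
#' Treats skeleton pixels as an 8-connected weighted graph (step weights 1
#' and sqrt(2)) and returns the pixel sequence of the longest shortest path
#' (the graph "diameter" path, found by double sweep). Side branches of a
#' skeleton are thereby pruned. Deterministic: ties resolve to the lowest
#' pixel index.
#'
#' @param skel Logical skeleton matrix.
#' @return Two-column matrix of (row, col) pixel coordinates along the
#'   path, or `NULL` for an empty skeleton.
#' @keywords internal
skeleton_longest_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(NULL)
  if (n == 1L) return(idx)
  nr <- nrow(skel)
  key <- (idx[, 2] - 1L) * nr + idx[, 1]
  lookup <- integer(length(skel))
  lookup[key] <- seq_len(n)
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  from <- to <- integer(0); w <- numeric(0)
  for (k in 1:4) {
    r2 <- idx[, 1] + offs[k, 1]; c2 <- idx[, 2] + offs[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skel)
    key2 <- (c2 - 1L) * nr + r2
    ok[ok] <- skel[key2[ok]]
    if (!any(ok)) next
    from <- c(from, which(ok))
    to <- c(to, lookup[key2[ok]])
    w <- c(w, rep(sqrt(sum(offs[k, ]^2)), sum(ok)))
  }
  if (!length(from)) return(idx[1L, , drop = FALSE])
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  d <- igraph::distances(g, v = 1L)
  d[!is.finite(d)] <- -1
  u <- which.max(d)
  d <- igraph::distances(g, v = u)
  d[!is.finite(d)] <- -1
  v <- which.max(d)
  path <- suppressWarnings(
    igraph::shortest_paths(g, from = u, to = v, output = "vpath")$vpath[[1L]]
  )
  idx[as.integer(path), , drop = FALSE]
}

#' Distance-transform ridge: pixels that are >= all 8 neighbours
#' @noRd
dt_ridge <- function(dt) {
  ridge <- matrix(TRUE, nrow(dt), ncol(dt))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ridge <- ridge & dt >= shift_mat(dt, dr, dc)
  }
  ridge & dt > 0
}

#' @noRd
cell_excluded <- function(cell_id, reason) {
  stop(structure(
    class = c("septalink_cell_excluded", "error", "condition"),
    list(message = sprintf("cell %s excluded: %s", cell_id, reason),
         call = NULL, cell_id = cell_id, reason = reason)
  ))
}

#' Extract the medial axis of one segmented cell
#'
#' Builds a single open pole-to-pole centerline for a labelled cell: the
#' mask is skeletonised by homotopic thinning ([skeletonize()]), the
#' skeleton is pruned to its longest geodesic path, the path is smoothed by
#' a moving average, resampled to ~1 px arc spacing, and extended at both
#' ends along the local tangent until it reaches the cell boundary. The
#' result is deterministic for a fixed mask.
#'
#' Cells are excluded (error of class `septalink_cell_excluded`, with a
#' `reason` field) when they touch the image border, have fewer than
#' `min_area` pixels, or are not elongated (disc- or ring-like masks whose
#' pruned skeleton is shorter than the cell width).
#'
#' @param mask Integer label matrix (0 = background).
#' @param cell_id Label of the cell to process.
#' @param min_area Minimum pixel area (default 20).
#' @param smooth_window Moving-average window for smoothing, in axis points
#'   (default 5).
#' @return An n x 2 matrix of (x, y) axis coordinates (columns `x`, `y`,
#'   ~1 px apart), with attributes `cell_id`, `arc_length_px` and
#'   `max_dt_px` (maximum distance-transform value, i.e. half the maximal
#'   cell width).
#' @export
extract_cell_axis <- function(mask, cell_id, min_area = 20L,
                              smooth_window = 5L) {
  bb <- cell_bbox(mask, cell_id)
  idx <- bb$idx
  if (nrow(idx) < min_area) cell_excluded(cell_id, "area below minimum")
  if (min(idx[, 1]) <= 1L || min(idx[, 2]) <= 1L ||
      max(idx[, 1]) >= nrow(mask) || max(idx[, 2]) >= ncol(mask))
    cell_excluded(cell_id, "touches image border")
  crop <- mask[bb$rows, bb$cols] == cell_id
  dt <- euclid_dt(crop)
  max_dt <- max(dt)
  skel <- skeletonize(crop, anchor = dt_ridge(dt) & crop)
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 2L)
    cell_excluded(cell_id, "degenerate skeleton")
  xy <- cbind(x = path[, 2], y = path[, 1])
  ## a rod's pruned skeleton spans ~(length - width); a disc's collapses to
  ## a few pixels, far below its radius (= max_dt)
  if (polyline_length(xy) < max_dt)
    cell_excluded(cell_id, "not elongated (skeleton shorter than cell width)")
  xy <- cbind(x = smooth_ma(xy[, 1], smooth_window),
              y = smooth_ma(xy[, 2], smooth_window))
  xy <- resample_polyline(xy, 1)
  xy <- extend_to_boundary(xy, crop, max_steps = ceiling(4 * max_dt / 0.25))
  xy <- resample_polyline(xy, 1)
  ## resampling can round an end point just across the boundary; keep the
  ## longest contiguous interior run so the axis lies strictly inside
  inc <- in_cell(crop, TRUE, xy[, 1], xy[, 2])
  if (!all(inc)) {
    r <- rle(inc)
    ends <- cumsum(r$lengths)
    k <- which(r$values)[which.max(r$lengths[r$values])]
    xy <- xy[(ends[k] - r$lengths[k] + 1L):ends[k], , drop = FALSE]
  }
  if (nrow(xy) < 3L) cell_excluded(cell_id, "degenerate axis")
  xy[, 1] <- xy[, 1] + bb$cols[1L] - 1
  xy[, 2] <- xy[, 2] + bb$rows[1L] - 1
  structure(xy, cell_id = cell_id,
            arc_length_px = polyline_length(xy), max_dt_px = max_dt,
            dt_crop = dt, dt_offset = c(x = bb$cols[1L], y = bb$rows[1L]))
}

#' Prolong a polyline along its end tangents while inside a mask
#' @noRd
extend_to_boundary <- function(xy, crop, step = 0.25, max_steps = 100L) {
  one_end <- function(p_end, p_in) {
    v <- p_end - p_in
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) return(NULL)
    v <- v / nv
    pts <- NULL
    p <- p_end
    for (i in seq_len(max_steps)) {
      q <- p_end + i * step * v
      if (!in_cell(crop, TRUE, q[1L], q[2L])) break
      pts <- rbind(pts, q)
    }
    pts
  }
  n <- nrow(xy)
  k <- min(4L, n - 1L)
  head_ext <- one_end(xy[1L, ], xy[1L + k, ])
  tail_ext <- one_end(xy[n, ], xy[n - k, ])
  out <- xy
  if (!is.null(head_ext)) out <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], out)
  if (!is.null(tail_ext)) out <- rbind(out, tail_ext)
  colnames(out) <- c("x", "y")
  out
}
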