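#' Parameters for the synthetic rod-cell image generator
#'
#' Study conditions for the fluorescence simulator: rod-shaped
#' (spherocylindrical) cells with a cytoplasmic fluorophore level and an
#' optional Gaussian septal band at midcell, imaged at a stated pixel size
#' with Poisson photon noise plus Gaussian read noise.
#'
#' @param n_cells Number of cells (default 50).
#' @param length_mean,length_sd,length_min Cell length distribution in
#'   micrometres (Gaussian, truncated below; defaults 3.0, 0.6, 1.8).
#' @param width_mean,width_sd Cell width distribution in micrometres
#'   (defaults 1.0, 0.05).
#' @param pixel_size Micrometres per pixel. Default 0.065 (100x objective
#'   on a small-pixel sCMOS); use 0.1 for the EMCCD preset.
#' @param cyto_level Mean cytoplasmic signal, photons per pixel
#'   (default 200).
#' @param enrichment Septal enrichment factor >= 1: the band peak is
#'   `enrichment * cyto_level`, i.e. the band adds
#'   `(enrichment - 1) * cyto_level` at its centre (default 2). A scalar,
#'   or one value per cell.
#' @param septal_sigma_um Gaussian sigma of the midcell band along the
#'   axis, micrometres (default 0.1, roughly the width of a diffraction-
#'   limited septal ring).
#' @param membrane_level Peak signal of the membrane channel at the cell
#'   outline, photons (default 300).
#' @param background Camera background offset, photons (default 10).
#' @param read_noise_sd Gaussian read noise SD, photons (default 2).
#' @param poisson_noise Apply Poisson photon noise? (default TRUE)
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `cell_sim_params`.
#' @export
cell_sim_params <- function(n_cells = 50L,
                            length_mean = 3.0, length_sd = 0.6,
                            length_min = 1.8,
                            width_mean = 1.0, width_sd = 0.05,
                            pixel_size = 0.065,
                            cyto_level = 200,
                            enrichment = 2,
                            septal_sigma_um = 0.1,
                            membrane_level = 300,
                            background = 10,
                            read_noise_sd = 2,
                            poisson_noise = TRUE,
                            seed = 1L) {
  p <- as.list(environment())
  if (any(p$enrichment < 1)) stop("`enrichment` must be >= 1")
  if (p$pixel_size <= 0) stop("`pixel_size` must be positive")
  if (!length(p$enrichment) %in% c(1L, p$n_cells))
    stop("`enrichment` must be a scalar or one value per cell")
  structure(p, class = "cell_sim_params")
}

#' Simulate fluorescence images of rod-shaped cells with a septal band
#'
#' Generates a label mask, a cytoplasmic/septal channel and a membrane
#' channel for `n_cells` randomly oriented 2-D spherocylinders. Cells are
#' placed on a jittered grid whose spacing guarantees that no cell overlaps
#' another or touches the image border (an invariant the downstream
#' pipeline relies on), with random orientation and sub-grid jitter. The
#' signal channel is `cyto_level` inside the cell plus a Gaussian midcell
#' band of amplitude `(enrichment - 1) * cyto_level`, then Poisson and
#' Gaussian read noise on top of a constant background. The mask is the
#' noiseless interior labelling.
#'
#' @param params A [cell_sim_params()] object.
#' @return A list with `mask` (integer label matrix), `gfp` and `membrane`
#'   (numeric matrices, photons) and `truth` (list: `params`, `seed`, and a
#'   per-cell tibble with planted centre, orientation, length, width and
#'   enrichment).
#' @export
simulate_cells <- function(params = cell_sim_params()) {
  stopifnot(inherits(params, "cell_sim_params"))
  withr::with_seed(params$seed, simulate_cells_impl(params))
}

#' @noRd
simulate_cells_impl <- function(p) {
  n <- p$n_cells
  len_um <- pmax(p$length_min, rnorm(n, p$length_mean, p$length_sd))
  wid_um <- pmax(0.4, rnorm(n, p$width_mean, p$width_sd))
  enr <- rep(p$enrichment, length.out = n)
  len_px <- len_um / p$pixel_size
  wid_px <- wid_um / p$pixel_size
  sig_px <- p$septal_sigma_um / p$pixel_size

  ## jittered-grid placement: spacing leaves >= 3 px clearance for the
  ## longest admissible cell at any orientation
  spacing <- ceiling(max(len_px) + max(wid_px) + 8)
  n_side <- ceiling(sqrt(n))
  dim_px <- n_side * spacing + 2L
  mask <- matrix(0L, dim_px, dim_px)
  gfp <- matrix(0, dim_px, dim_px)
  mem <- matrix(0, dim_px, dim_px)
  jit_max <- 2
  cells <- vector("list", n)
  for (k in seq_len(n)) {
    gi <- (k - 1L) %% n_side
    gj <- (k - 1L) %/% n_side
    cx <- gi * spacing + spacing / 2 + 1 + runif(1L, -jit_max, jit_max)
    cy <- gj * spacing + spacing / 2 + 1 + runif(1L, -jit_max, jit_max)
    th <- runif(1L, 0, pi)
    half <- pmax(0, (len_px[k] - wid_px[k]) / 2)   # capsule segment half-length
    r <- wid_px[k] / 2
    x0 <- max(1L, floor(cx - len_px[k] / 2 - 2))
    x1 <- min(dim_px, ceiling(cx + len_px[k] / 2 + 2))
    y0 <- max(1L, floor(cy - len_px[k] / 2 - 2))
    y1 <- min(dim_px, ceiling(cy + len_px[k] / 2 + 2))
    xs <- x0:x1; ys <- y0:y1
    px <- outer(rep(1, length(ys)), xs) - cx
    py <- outer(ys, rep(1, length(xs))) - cy
    u <- cos(th) * px + sin(th) * py          # axial coordinate from centre
    v <- -sin(th) * px + cos(th) * py
    du <- pmax(abs(u) - half, 0)
    d <- sqrt(du^2 + v^2)
    inside <- d <= r
    if (any(mask[ys, xs][inside] != 0L))
      stop("internal error: overlapping cell placement")
    band <- (enr[k] - 1) * exp(-u^2 / (2 * sig_px^2))
    sub_g <- gfp[ys, xs]
    sub_g[inside] <- p$cyto_level * (1 + band[inside])
    gfp[ys, xs] <- sub_g
    shell <- inside & d >= r - 1
    sub_m <- mem[ys, xs]
    sub_m[shell] <- p$membrane_level
    mem[ys, xs] <- sub_m
    sub_k <- mask[ys, xs]
    sub_k[inside] <- k
    mask[ys, xs] <- sub_k
    cells[[k]] <- tibble(cell_id = k, cx = cx, cy = cy, theta = th,
                         length_um = len_um[k], width_um = wid_um[k],
                         enrichment = enr[k])
  }
  add_noise <- function(img) {
    img <- img + p$background
    if (p$poisson_noise) img <- matrix(rpois(length(img), img), nrow(img))
    if (p$read_noise_sd > 0)
      img <- img + rnorm(length(img), 0, p$read_noise_sd)
    img
  }
  list(mask = mask, gfp = add_noise(gfp), membrane = add_noise(mem),
       truth = list(params = unclass(p), seed = p$seed,
                    cells = dplyr::bind_rows(cells)))
}

#' Write a simulated cell dataset as TIFF files plus a truth record
#'
#' Writes `mask.tif` (16-bit integer labels), `gfp.tif` and `membrane.tif`
#' (16-bit, photons clamped to \[0, 65535\]) and `truth.json` into `dir`.
#' Regeneration from the same seed is byte-identical.
#'
#' @param sim Result of [simulate_cells()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cell_tiffs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  to16 <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  paths <- c(mask = file.path(dir, "mask.tif"),
             gfp = file.path(dir, "gfp.tif"),
             membrane = file.path(dir, "membrane.tif"),
             truth = file.path(dir, "truth.json"))
  tiff::writeTIFF(to16(sim$mask), paths["mask"], bits.per.sample = 16L)
  tiff::writeTIFF(to16(sim$gfp), paths["gfp"], bits.per.sample = 16L)
  tiff::writeTIFF(to16(sim$membrane), paths["membrane"], bits.per.sample = 16L)
  truth <- sim$truth
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a simulated cell dataset written by [write_cell_tiffs()]
#'
#' @param dir Directory containing `mask.tif`, `gfp.tif`, `membrane.tif`.
#' @return A list with `mask` (integer labels), `gfp`, `membrane`
#'   (photon-scale matrices).
#' @export
read_cell_tiffs <- function(dir) {
  rd <- function(f) round(tiff::readTIFF(file.path(dir, f)) * 65535)
  m <- rd("mask.tif")
  list(mask = matrix(as.integer(m), nrow = nrow(m)),
       gfp = rd("gfp.tif"), membrane = rd("membrane.tif"))
}
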