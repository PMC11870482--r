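#' Default glycan fragment panel with pairwise-distinct masses
#'
#' A panel of glycan fragments spanning the products of lytic-
#' transglycosylase and muramidase digestion of (partly deacetylated)
#' denuded strands: the six free sugar units, six disaccharides covering
#' every acetylation state with and without the 1,6-anhydro end, and
#' tetrasaccharides of decreasing acetylation. Compositions are chosen so
#' that all neutral masses are pairwise distinct (isomeric pairs such as
#' GlcNAc-MurN / GlcN-MurNAc, which share an elemental formula, are
#' represented once).
#'
#' @param n Number of fragments to return, up to 22 (default 20).
#' @return Named list of [glycan_fragment()] objects.
#' @export
default_fragment_panel <- function(n = 20L) {
  frag <- function(...) glycan_fragment(c(...))
  panel <- list(
    ## free units
    GlcNAc = frag("GlcNAc"), GlcN = frag("GlcN"),
    MurNAc = frag("MurNAc"), anhMurNAc = frag("anhMurNAc"),
    MurN = frag("MurN"), anhMurN = frag("anhMurN"),
    ## disaccharides, anhydro (lytic transglycosylase products)
    `GlcNAc-MurNAcAnh` = frag("GlcNAc", "anhMurNAc"),
    `GlcN-MurNAcAnh` = frag("GlcN", "anhMurNAc"),
    `GlcN-MurNAnh` = frag("GlcN", "anhMurN"),
    ## disaccharides, reducing (muramidase products)
    `GlcNAc-MurNAc` = frag("GlcNAc", "MurNAc"),
    `GlcN-MurNAc` = frag("GlcN", "MurNAc"),
    `GlcN-MurN` = frag("GlcN", "MurN"),
    ## tetrasaccharides, anhydro, acetylation 4 -> 0
    `(GlcNAc-MurNAc)GlcNAc-MurNAcAnh` =
      frag("GlcNAc", "MurNAc", "GlcNAc", "anhMurNAc"),
    `(GlcN-MurNAc)GlcNAc-MurNAcAnh` =
      frag("GlcN", "MurNAc", "GlcNAc", "anhMurNAc"),
    `(GlcN-MurN)GlcNAc-MurNAcAnh` =
      frag("GlcN", "MurN", "GlcNAc", "anhMurNAc"),
    `(GlcN-MurN)GlcN-MurNAcAnh` =
      frag("GlcN", "MurN", "GlcN", "anhMurNAc"),
    `(GlcN-MurN)GlcN-MurNAnh` =
      frag("GlcN", "MurN", "GlcN", "anhMurN"),
    ## tetrasaccharides, reducing
    `(GlcNAc-MurNAc)2` = frag("GlcNAc", "MurNAc", "GlcNAc", "MurNAc"),
    `(GlcN-MurNAc)GlcNAc-MurNAc` =
      frag("GlcN", "MurNAc", "GlcNAc", "MurNAc"),
    `(GlcN-MurN)GlcNAc-MurNAc` =
      frag("GlcN", "MurN", "GlcNAc", "MurNAc"),
    `(GlcN-MurN)GlcN-MurNAc` =
      frag("GlcN", "MurN", "GlcN", "MurNAc"),
    `(GlcN-MurN)2` = frag("GlcN", "MurN", "GlcN", "MurN")
  )
  if (n > length(panel))
    stop("default panel has at most ", length(panel), " fragments")
  panel[seq_len(n)]
}

#' Simulate an LC-MS peak list from a fragment panel
#'
#' Observed m/z values are the theoretical singly-protonated m/z of each
#' fragment perturbed by multiplicative Gaussian noise of the stated ppm
#' magnitude; intensities are drawn log-uniformly.
#'
#' @param panel Named list of [glycan_fragment()] objects (default
#'   [default_fragment_panel()]).
#' @param abundances Optional intensities (one per fragment); drawn
#'   log-uniformly in \[1e4, 1e6\] when `NULL`.
#' @param ppm_sigma SD of the relative m/z error in ppm (>= 0, default 5).
#' @param seed Integer seed.
#' @return A list with `peaks` (tibble `mz`, `intensity`) and `truth`
#'   (tibble `peak`, `fragment`, `true_mz`, plus `ppm_sigma` and `seed`).
#' @export
simulate_peaks <- function(panel = default_fragment_panel(),
                           abundances = NULL, ppm_sigma = 5, seed = 1L) {
  stopifnot(ppm_sigma >= 0, length(panel) >= 1L)
  withr::with_seed(seed, {
    nm <- names(panel)
    if (is.null(nm)) nm <- vapply(panel, function(f) f$name, character(1L))
    true_mz <- vapply(panel, function(f)
      mz_value(monoisotopic_mass(f), 1L), numeric(1L))
    if (is.null(abundances))
      abundances <- 10^runif(length(panel), 4, 6)
    stopifnot(length(abundances) == length(panel))
    obs <- unname(true_mz * (1 + rnorm(length(panel), 0, ppm_sigma * 1e-6)))
    list(
      peaks = tibble(mz = obs, intensity = unname(abundances)),
      truth = list(
        assignments = tibble(peak = seq_along(panel), fragment = unname(nm),
                             true_mz = unname(true_mz)),
        ppm_sigma = ppm_sigma, seed = seed
      )
    )
  })
}

#' Simulate an amidase-assay peak-area table pair
#'
#' Produces a control area table and a sample table in which every peak
#' area is the control area times a planted inhibition factor, with
#' multiplicative Gaussian noise of the stated coefficient of variation.
#' Negative draws are resampled (bounded retries).
#'
#' @param control_areas Named numeric vector (or `peak_id`/`area` data
#'   frame) of control peak areas, all positive.
#' @param inhibition_factor Planted sample/control area ratio (default
#'   0.4).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.1).
#' @param n_replicates Number of sample replicates (default 3).
#' @param seed Integer seed.
#' @return A list with `control` (tibble `peak_id`, `area`), `sample`
#'   (tibble `peak_id`, `area`, `replicate`) and `truth` (list with the
#'   planted factor, cv and seed).
#' @export
simulate_assay <- function(control_areas, inhibition_factor = 0.4,
                           noise_cv = 0.1, n_replicates = 3L, seed = 1L) {
  ctrl <- as_area_table(control_areas)
  if (any(ctrl$area <= 0)) stop("control areas must all be positive")
  stopifnot(inhibition_factor >= 0, noise_cv >= 0)
  withr::with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      a <- ctrl$area * inhibition_factor * (1 + rnorm(nrow(ctrl), 0, noise_cv))
      for (tries in seq_len(100L)) {
        neg <- a < 0
        if (!any(neg)) break
        a[neg] <- ctrl$area[neg] * inhibition_factor *
          (1 + rnorm(sum(neg), 0, noise_cv))
      }
      if (any(a < 0)) stop("could not draw non-negative areas; reduce noise_cv")
      tibble(peak_id = ctrl$peak_id, area = a, replicate = r)
    })
    list(control = ctrl, sample = dplyr::bind_rows(reps),
         truth = list(inhibition_factor = inhibition_factor,
                      noise_cv = noise_cv, n_replicates = n_replicates,
                      seed = seed))
  })
}
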