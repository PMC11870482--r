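#' Read an LC-MS peak list from CSV
#'
#' Expects columns `mz` (required, Th), `intensity` and `rt` (optional).
#'
#' @param path Path to a CSV file.
#' @return A tibble of peaks.
#' @export
read_peaks_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_peaks(df)
}

#' @noRd
validate_peaks <- function(peaks) {
  peaks <- as_tibble(peaks)
  if (!"mz" %in% names(peaks)) stop("peak table needs an `mz` column")
  if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0))
    stop("all m/z values must be positive")
  if ("intensity" %in% names(peaks) && any(peaks$intensity < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  peaks
}

#' Assign LC-MS peaks to a panel of candidate glycan fragments
#'
#' Matches every observed peak against the theoretical protonated m/z of
#' every candidate fragment and charge state `1..z_max`. A peak is assigned
#' to each candidate whose theoretical m/z lies within `tolerance_ppm`; when
#' several match, the assignment with the smallest absolute ppm error is
#' flagged `best`. Peaks with no match within tolerance are listed in the
#' `"unassigned"` attribute.
#'
#' @param peaks Data frame with column `mz` (Th), optionally `intensity`,
#'   `rt`.
#' @param candidates List of [glycan_fragment()] objects (or character
#'   vectors of unit names), optionally named.
#' @param tolerance_ppm Mass tolerance in parts per million (> 0).
#' @param z_max Maximum charge state considered (default 1).
#' @return A tibble with one row per (peak, candidate, z) match: `peak`,
#'   `mz`, `fragment`, `z`, `theoretical_mz`, `error_ppm`, `best`; attribute
#'   `unassigned` holds the row indices of unmatched peaks.
#' @export
assign_peaks <- function(peaks, candidates, tolerance_ppm, z_max = 1L) {
  peaks <- validate_peaks(peaks)
  if (!length(candidates)) stop("`candidates` must not be empty")
  if (!is.list(candidates) || inherits(candidates, "glycan_fragment"))
    candidates <- list(candidates)
  candidates <- lapply(candidates, function(f)
    if (inherits(f, "glycan_fragment")) f else glycan_fragment(f))
  stopifnot(is.numeric(tolerance_ppm), tolerance_ppm > 0)
  frag_names <- names(candidates)
  if (is.null(frag_names)) frag_names <- rep("", length(candidates))
  frag_names <- ifelse(nzchar(frag_names), frag_names,
                       vapply(candidates, function(f) f$name, character(1L)))
  masses <- vapply(candidates, monoisotopic_mass, numeric(1L))
  theo <- expand.grid(cand = seq_along(candidates), z = seq_len(z_max))
  theo$mz <- mz_value(masses[theo$cand], theo$z)

  hits <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    err <- (peaks$mz[i] - theo$mz) / theo$mz * 1e6
    ok <- which(abs(err) <= tolerance_ppm)
    if (!length(ok)) next
    best <- ok[which.min(abs(err[ok]))]
    hits[[i]] <- tibble(
      peak = i,
      mz = peaks$mz[i],
      fragment = frag_names[theo$cand[ok]],
      z = as.integer(theo$z[ok]),
      theoretical_mz = theo$mz[ok],
      error_ppm = err[ok],
      best = ok == best
    )
  }
  out <- dplyr::bind_rows(hits)
  if (!nrow(out))
    out <- tibble(peak = integer(), mz = numeric(), fragment = character(),
                  z = integer(), theoretical_mz = numeric(),
                  error_ppm = numeric(), best = logical())
  attr(out, "unassigned") <- setdiff(seq_len(nrow(peaks)), unique(out$peak))
  out
}

#' Find peak pairs separated by the acetyl mass shift
#'
#' Scans all unordered pairs of peaks for an m/z difference equal to the
#' acetyl-group mass (C2H2O, 42.0105646 Da; singly-charged ions assumed).
#' Such pairs flag a putative N-deacetylation product: the lighter peak is
#' the deacetylated candidate of the heavier one.
#'
#' @param peaks Data frame with column `mz` (at least 2 rows).
#' @param tolerance_ppm Tolerance on the difference, in ppm of the heavier
#'   peak's m/z (default 10).
#' @return A tibble with `mz_light`, `mz_heavy`, `delta_mz`,
#'   `deacetylated_candidate` (= `mz_light`).
#' @export
find_deacetylation_pairs <- function(peaks, tolerance_ppm = 10) {
  peaks <- validate_peaks(peaks)
  if (nrow(peaks) < 2L) stop("need at least two peaks")
  acetyl <- mass_constants()$acetyl_delta
  cmb <- combn(sort(peaks$mz), 2L)
  delta <- cmb[2L, ] - cmb[1L, ]
  ok <- abs(delta - acetyl) <= tolerance_ppm * 1e-6 * cmb[2L, ]
  tibble(
    mz_light = cmb[1L, ok],
    mz_heavy = cmb[2L, ok],
    delta_mz = delta[ok],
    deacetylated_candidate = cmb[1L, ok]
  )
}

#' Relative HPLC peak areas against a no-enzyme control
#'
#' Expresses each sample peak area as a percentage of the same peak's area
#' in a control reaction (100 x sample/control), the standard end-point
#' readout for amidase assays. Peaks absent from the sample report 0%;
#' sample peaks absent from the control are not scaled and are returned in
#' the `"unmatched_sample_peaks"` attribute (with a warning).
#'
#' @param sample_areas,control_areas Data frames with columns `peak_id` and
#'   `area`, or named numeric vectors.
#' @return A tibble with `peak_id`, `control_area`, `sample_area`,
#'   `percent`, one row per control peak.
#' @export
relative_peak_areas <- function(sample_areas, control_areas) {
  sample_areas <- as_area_table(sample_areas)
  control_areas <- as_area_table(control_areas)
  if (anyDuplicated(control_areas$peak_id) || anyDuplicated(sample_areas$peak_id))
    stop("peak_id must be unique within each area table")
  if (any(!is.finite(control_areas$area)) || any(control_areas$area <= 0))
    stop("control areas must all be positive")
  idx <- match(control_areas$peak_id, sample_areas$peak_id)
  samp <- ifelse(is.na(idx), 0, sample_areas$area[idx])
  unmatched <- setdiff(sample_areas$peak_id, control_areas$peak_id)
  if (length(unmatched))
    warning("sample peak(s) absent from control were not scaled: ",
            paste(unmatched, collapse = ", "))
  out <- tibble(
    peak_id = control_areas$peak_id,
    control_area = control_areas$area,
    sample_area = samp,
    percent = 100 * samp / control_areas$area
  )
  attr(out, "unmatched_sample_peaks") <- unmatched
  out
}

#' @noRd
as_area_table <- function(x) {
  if (is.numeric(x) && !is.null(names(x)))
    return(tibble(peak_id = names(x), area = as.numeric(x)))
  x <- as_tibble(x)
  if (!all(c("peak_id", "area") %in% names(x)))
    stop("area tables need columns `peak_id` and `area`")
  x$peak_id <- as.character(x$peak_id)
  x
}
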