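#' Construct a microscope field image
#'
#' @param pixels Numeric matrix of 16-bit intensities (rows = y, cols = x),
#'   values in \[0, 65535\], both dimensions at least 16 px.
#' @param pixel_size_um Physical pixel pitch in micrometres (> 0).
#' @param channel Stain label, one of `TCRab`, `ED1`, `S100`, `ATF3`,
#'   `DAPI`.
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size_um,
                        channel = c("TCRab", "ED1", "S100", "ATF3", "DAPI")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || min(dim(pixels)) < 16L) {
    stop("pixels must be a matrix with both dimensions >= 16", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 65535) {
    stop("intensities must lie in [0, 65535]", call. = FALSE)
  }
  stopifnot(pixel_size_um > 0)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel),
            class = "field_image")
}

#' Read a 16-bit grayscale TIFF as a field image
#'
#' @param path Path to the TIFF file.
#' @inheritParams field_image
#' @return A [field_image()].
#' @export
read_field_tiff <- function(path, pixel_size_um, channel = "TCRab") {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  field_image(round(m * 65535), pixel_size_um, channel)
}

#' Otsu threshold of an intensity matrix
#'
#' Maximises between-class variance over a 256-bin histogram of the
#' intensity range, the standard automatic two-class threshold used for
#' densitometry of stained sections.
#'
#' @param pixels Numeric matrix of intensities.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold on the intensity scale of `pixels`.
#' @export
otsu_threshold <- function(pixels, levels = 256L) {
  rng <- range(pixels)
  if (diff(rng) == 0) {
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- tabulate(findInterval(pixels, breaks, rightmost.closed = TRUE),
                     nbins = levels)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  # the criterion plateaus across empty histogram regions; take the plateau
  # midpoint, as ImageJ-style auto-thresholding does
  peak <- which(between >= max(between) - 1e-9 * max(between))
  mids[round(mean(range(peak)))]
}

#' Percent immunoreactive area of a field
#'
#' Fraction of field pixels above an intensity threshold, the densitometry
#' measure used where individual stained cells cannot be resolved (dense
#' macrophage infiltrates, Schwann-cell S100). The threshold is chosen
#' automatically by Otsu's method (default) or supplied as a fixed value.
#' A constant image has no Otsu threshold; it is reported as 0 % with a
#' degenerate flag and a warning.
#'
#' @param image A [field_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold intensity when `method = "fixed"`.
#' @return List of class `densitometry_result`: `percent_ir`,
#'   `threshold_value`, `degenerate`.
#' @export
percent_ir_area <- function(image, method = c("otsu", "fixed"),
                            fixed_value = NULL) {
  stopifnot(inherits(image, "field_image"))
  method <- match.arg(method)
  px <- image$pixels
  if (method == "fixed") {
    stopifnot(is.numeric(fixed_value), length(fixed_value) == 1L)
    thr <- fixed_value
    degenerate <- FALSE
  } else {
    if (diff(range(px)) == 0) {
      warning("constant image: returning 0 % immunoreactive area")
      return(structure(list(percent_ir = 0, threshold_value = NA_real_,
                            degenerate = TRUE),
                       class = "densitometry_result"))
    }
    thr <- otsu_threshold(px)
    degenerate <- FALSE
  }
  structure(list(percent_ir = 100 * mean(px > thr), threshold_value = thr,
                 degenerate = degenerate),
            class = "densitometry_result")
}

# 8-connectivity connected-component labelling of a logical mask.
# Foreground pixels become graph vertices joined to their 8-neighbours;
# components come from igraph. Returns an integer matrix of labels (0 =
# background).
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  idx <- which(mask)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(labels)
  nr <- nrow(mask)
  vid <- integer(length(mask)); vid[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  # shifts covering each undirected 8-neighbour pair once
  for (s in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ok <- row + s[1] >= 1L & row + s[1] <= nr & col + s[2] <= ncol(mask)
    nb <- idx[ok] + s[1] + s[2] * nr
    hit <- mask[nb]
    if (any(hit)) {
      edges <- c(edges, rbind(vid[idx[ok][hit]], vid[nb[hit]]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  labels[idx] <- igraph::components(g)$membership
  labels
}

#' Count stained cells in a field
#'
#' Automated replacement for manual spot counting: thresholds the field at
#' `intensity_floor`, labels 8-connected components, and counts those whose
#' equivalent radius (radius of the circle with the component's pixel area)
#' falls within the given physical bounds. Deterministic for a given image.
#'
#' @param image A [field_image()].
#' @param min_radius_um,max_radius_um Equivalent-radius acceptance window in
#'   micrometres.
#' @param intensity_floor Minimum intensity for a pixel to count as signal.
#' @return Integer count of detected cells.
#' @export
count_cells <- function(image, min_radius_um = 1, max_radius_um = 8,
                        intensity_floor = 10000) {
  stopifnot(inherits(image, "field_image"))
  if (min_radius_um >= max_radius_um) {
    stop("min_radius_um must be smaller than max_radius_um", call. = FALSE)
  }
  labels <- label_components(image$pixels > intensity_floor)
  if (max(labels) == 0L) return(0L)
  areas_px <- tabulate(labels[labels > 0L])
  r_um <- sqrt(areas_px / pi) * image$pixel_size_um
  sum(r_um >= min_radius_um & r_um <= max_radius_um)
}

#' Cell density over a sampled field set
#'
#' Converts a total cell count over `n_fields` fields into cells per mm2,
#' the normalisation used when counts from 12 random fields are pooled per
#' animal.
#'
#' @param total_count Total cells counted across all fields.
#' @param n_fields Number of fields sampled (>= 1).
#' @param field_area_mm2 Area of one field in mm2 (> 0).
#' @return List of class `density_result`: `total_count`, `n_fields`,
#'   `field_area_mm2`, `density` (cells/mm2).
#' @export
cells_per_mm2 <- function(total_count, n_fields, field_area_mm2) {
  stopifnot(total_count >= 0, n_fields >= 1, field_area_mm2 > 0)
  structure(list(total_count = total_count, n_fields = n_fields,
                 field_area_mm2 = field_area_mm2,
                 density = total_count / (n_fields * field_area_mm2)),
            class = "density_result")
}

#' S100 injury/proximal densitometry ratio
#'
#' Mean percent-immunoreactive area at the injury site divided by the mean
#' at an uninjured proximal site of the same nerve. Intact nerves stain
#' uniformly, so the ratio is about 1 in shams; demyelination at the injury
#' site pushes it below 1.
#'
#' @param injury_fields,proximal_fields Lists of `densitometry_result`
#'   objects (typically 8 fields each).
#' @return The ratio (unitless).
#' @export
s100_ratio <- function(injury_fields, proximal_fields) {
  get_pct <- function(fields, what) {
    if (!length(fields)) stop("no ", what, " fields", call. = FALSE)
    vapply(fields, function(f) f$percent_ir, numeric(1))
  }
  inj <- mean(get_pct(injury_fields, "injury"))
  prox <- mean(get_pct(proximal_fields, "proximal"))
  if (prox <= 0) {
    stop("mean proximal %IR is zero: ratio undefined", call. = FALSE)
  }
  inj / prox
}

#' ATF3-positive nuclear fraction
#'
#' Percentage of DRG neurons with ATF3-immunoreactive nuclei, normalising
#' for the number of neurons counted; at least 300 neurons must have been
#' assessed per animal for the fraction to be reported.
#'
#' @param positive_nuclei Count of ATF3-positive nuclei.
#' @param total_neurons Total neurons counted (>= 300).
#' @return Percentage in \[0, 100\].
#' @export
atf3_fraction <- function(positive_nuclei, total_neurons) {
  if (total_neurons < 300) {
    stop("fewer than 300 neurons assessed (", total_neurons,
         "): fraction not reportable", call. = FALSE)
  }
  if (positive_nuclei < 0 || positive_nuclei > total_neurons) {
    stop("positive_nuclei must lie in [0, total_neurons]", call. = FALSE)
  }
  100 * positive_nuclei / total_neurons
}

#' Aggregate electron-microscopy measurements
#'
#' Means of manually traced measurement lists: myelin thickness over the
#' measured axons (nominally 100 across ten micrographs) and axon counts
#' per 70 um2 field.
#'
#' @param thickness_um Myelin thickness measurements (um).
#' @param axon_counts Axon counts, one per field.
#' @param expected_axons Nominal number of thickness measurements; a
#'   warning is issued if fewer were provided.
#' @return List of class `em_summary`: `mean_myelin_thickness_um`,
#'   `mean_axon_count`, `n_axons_measured`, `n_fields`.
#' @export
summarize_em <- function(thickness_um, axon_counts, expected_axons = 100L) {
  if (!length(thickness_um) || !length(axon_counts)) {
    stop("empty measurement list", call. = FALSE)
  }
  if (any(thickness_um < 0) || any(axon_counts < 0)) {
    stop("measurements must be non-negative", call. = FALSE)
  }
  if (length(thickness_um) < expected_axons) {
    warning("only ", length(thickness_um), " of ", expected_axons,
            " expected myelin measurements provided")
  }
  structure(list(mean_myelin_thickness_um = mean(thickness_um),
                 mean_axon_count = mean(axon_counts),
                 n_axons_measured = length(thickness_um),
                 n_fields = length(axon_counts)),
            class = "em_summary")
}

#' Quantify T-lymphocyte density for every animal in a cohort
#'
#' Runs [count_cells()] over each animal's field set and pools counts into
#' cells per mm2.
#'
#' @param cohort A [generate_cohort()] result with fields included.
#' @param ... Passed to [count_cells()].
#' @return Data frame: `animal_id`, `group_truth`, `total_count`,
#'   `n_fields`, `density_mm2`, `true_density_mm2` (from the embedded
#'   ground truth).
#' @export
quantify_cohort_fields <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$fields)) {
    stop("cohort was generated without images", call. = FALSE)
  }
  area <- field_area_mm2(cohort$config$image_params)
  rows <- lapply(names(cohort$fields), function(id) {
    fs <- cohort$fields[[id]]
    counts <- vapply(fs, function(f) count_cells(f$image, ...), numeric(1))
    truth <- vapply(fs, function(f) f$true_count, numeric(1))
    dens <- cells_per_mm2(sum(counts), length(fs), area)
    data.frame(animal_id = id,
               group_truth =
                 cohort$animals$group_truth[cohort$animals$animal_id == id],
               total_count = dens$total_count, n_fields = dens$n_fields,
               density_mm2 = dens$density,
               true_density_mm2 = sum(truth) / (length(fs) * area))
  })
  do.call(rbind, rows)
}
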