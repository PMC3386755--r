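#' Random sequential adsorption of proteins onto a nanotube
#'
#' Builds a self-assembled protein monolayer on the cylinder surface by
#' random sequential adsorption (RSA): candidate positions (z, s) are drawn
#' uniformly on the unrolled surface, an attachment orientation is drawn with
#' probability proportional to its hydrophobic contact area, and the
#' placement is accepted iff its footprint overlaps no previously adsorbed
#' protein. Placements are never moved or removed. The run stops after
#' `stop_after_failures` consecutive rejections, the operational stand-in for
#' monolayer saturation (jamming).
#'
#' The arc coordinate is periodic with period pi * diameter; axial boundaries
#' are hard and each footprint must fit entirely on the tube.
#'
#' @param tube A [nanotube()].
#' @param protein A [protein_prism()]; ignored when `dim_ranges` is given.
#' @param orientations Data frame from [make_orientation_set()]; rows may be
#'   subset to restrict the allowed modes. Ignored when `dim_ranges` is given.
#' @param seed Integer seed; identical seeds give identical states.
#' @param stop_after_failures Consecutive-rejection count that ends the run.
#' @param dim_ranges Optional list with elements `edge_a`, `edge_b`,
#'   `thickness`, each a length-2 range in nm. When given, every attempted
#'   molecule draws its own dimensions uniformly within the ranges
#'   (per-molecule crystallographic jitter) and its orientation set is
#'   rebuilt accordingly.
#' @param cutoff Contact gap cutoff in nm (used when orientation sets are
#'   rebuilt under `dim_ranges`).
#' @return An object of class `adsorption_state`: list with `tube`,
#'   `placements` (data frame: z_nm, s_nm, mode, radial_extent_nm,
#'   footprint_axial_nm, footprint_arc_nm), `coverage_fraction`, `attempts`,
#'   `consecutive_failures`, `seed`.
#' @export
run_rsa <- function(tube, protein = protein_prism(),
                    orientations = make_orientation_set(protein, tube),
                    seed = 1L, stop_after_failures = 10000L,
                    dim_ranges = NULL, cutoff = 0.009) {
  stopifnot(inherits(tube, "nanotube"))
  if (stop_after_failures < 1) {
    stop("invalid parameter: stop_after_failures must be >= 1", call. = FALSE)
  }
  period <- pi * tube$diameter
  jitter <- !is.null(dim_ranges)
  if (!jitter) {
    ax_all <- orientations$footprint_axial_nm
    ar_all <- orientations$footprint_arc_nm
    re_all <- orientations$radial_extent_nm
    md_all <- orientations$mode
    prob <- orientation_probabilities(orientations)
    if (max(ax_all) > tube$length || max(ar_all) >= period) {
      stop("invalid parameter: footprint larger than the tube", call. = FALSE)
    }
  } else {
    lo <- vapply(dim_ranges, `[`, numeric(1), 1L)
    hi <- vapply(dim_ranges, `[`, numeric(1), 2L)
    if (max(hi) > tube$length || max(hi) >= period) {
      stop("invalid parameter: footprint larger than the tube", call. = FALSE)
    }
  }

  set.seed(seed)
  r <- tube$diameter / 2
  if (!jitter) {
    omat <- cbind(orientations$contact_area_A2, re_all, ax_all, ar_all)
    modes <- md_all
    rmat <- matrix(0, 3, 2)
  } else {
    omat <- matrix(0, 1, 4)
    modes <- c("lateral", "tri_face", "long_edge", "short_edge", "corner")
    rmat <- rbind(dim_ranges$edge_a, dim_ranges$edge_b, dim_ranges$thickness)
  }
  eng <- .rsa_engine(tube$length, period, as.integer(stop_after_failures),
                     omat, jitter, rmat, r, cutoff)
  pl <- eng$placements
  placements <- data.frame(
    z_nm = pl[, 1], s_nm = pl[, 2], mode = modes[pl[, 3]],
    radial_extent_nm = pl[, 4],
    footprint_axial_nm = pl[, 5], footprint_arc_nm = pl[, 6],
    stringsAsFactors = FALSE
  )
  attempts <- eng$attempts
  fails <- eng$fails
  structure(list(
    tube = tube,
    placements = placements,
    coverage_fraction = sum(placements$footprint_axial_nm *
                              placements$footprint_arc_nm) /
      (period * tube$length),
    attempts = attempts,
    consecutive_failures = fails,
    seed = seed
  ), class = "adsorption_state")
}

#' @export
print.adsorption_state <- function(x, ...) {
  cat(sprintf(
    "RSA state: %d proteins on a %.0f nm x %.1f nm (unrolled) tube surface\n",
    nrow(x$placements), x$tube$length, pi * x$tube$diameter))
  cat(sprintf("  coverage %.3f, %d attempts, seed %d\n",
              x$coverage_fraction, x$attempts, x$seed))
  invisible(x)
}

#' Adsorbed-layer thickness statistics
#'
#' Mean and standard deviation of the radial extents (how far each adsorbed
#' protein protrudes above the tube wall). For a saturated monolayer of
#' P450-sized prisms this lands between 3 and 6 nm.
#'
#' @param state An [run_rsa()] state.
#' @return List with `mean_nm`, `sd_nm`, `n`.
#' @export
layer_thickness_stats <- function(state) {
  stopifnot(inherits(state, "adsorption_state"))
  ext <- state$placements$radial_extent_nm
  if (length(ext) == 0L) {
    stop("empty state: no adsorbed proteins", call. = FALSE)
  }
  list(mean_nm = mean(ext),
       sd_nm = if (length(ext) > 1L) stats::sd(ext) else 0,
       n = length(ext))
}

#' SEM-style projected diameter profile of a coated tube
#'
#' Emulates the diameter measurement made on scanning-electron-microscopy
#' images: at each sampled axial position the apparent tube width is the bare
#' diameter plus the protrusion of the protein layer on each silhouette side.
#' Proteins are assigned to the top or bottom silhouette by the arc position
#' of their footprint centre; the protrusion on a side is the largest radial
#' extent among the proteins covering that axial position on that side (zero
#' if none).
#'
#' @param state An [run_rsa()] state.
#' @param n_axial_samples Number of evenly spaced axial sample positions.
#' @return Numeric vector of projected diameters in nm.
#' @export
projected_diameter_profile <- function(state, n_axial_samples = 100L) {
  stopifnot(inherits(state, "adsorption_state"))
  if (n_axial_samples < 1) {
    stop("invalid parameter: n_axial_samples must be >= 1", call. = FALSE)
  }
  zs <- seq(0, state$tube$length, length.out = n_axial_samples + 2L)
  zs <- zs[-c(1L, length(zs))]
  p <- state$placements
  if (nrow(p) == 0L) {
    return(rep(state$tube$diameter, length(zs)))
  }
  period <- pi * state$tube$diameter
  top <- p$s_nm < period / 2
  vapply(zs, function(z) {
    covers <- abs(z - p$z_nm) < p$footprint_axial_nm / 2
    t_top <- if (any(covers & top)) max(p$radial_extent_nm[covers & top]) else 0
    t_bot <- if (any(covers & !top)) max(p$radial_extent_nm[covers & !top]) else 0
    state$tube$diameter + t_top + t_bot
  }, numeric(1))
}

#' Ensemble Monte Carlo simulation of coated nanotubes
#'
#' Runs [run_rsa()] on `n_tubes` independent tubes (per-tube seeds derived as
#' `seed + tube index`), each adsorbed molecule drawing its dimensions
#' uniformly within the crystallographic ranges, and aggregates SEM-style
#' coated-diameter and layer-thickness statistics across the ensemble.
#'
#' @param n_tubes Number of independent tubes.
#' @param tube A [nanotube()]; defaults to 10 nm x 1000 nm.
#' @param dim_ranges Crystallographic dimension ranges (nm) for per-molecule
#'   jitter; defaults to 4.5--5 x 5--6.5 x 3.5--4.5.
#' @param cutoff Contact gap cutoff, nm.
#' @param seed Integer base seed.
#' @param stop_after_failures Jamming stopping rule per tube.
#' @param n_axial_samples Diameter sample positions per tube.
#' @return An object of class `coated_tube_stats`: list with `mean_diameter`,
#'   `sd_diameter`, `mean_thickness`, `sd_thickness`, `coverage_fraction`,
#'   `n_tubes`, `n_proteins`, `seed`.
#' @export
#' @examples
#' \donttest{
#' simulate_ensemble(n_tubes = 5, tube = nanotube(10, 300), seed = 42)
#' }
simulate_ensemble <- function(n_tubes = 50L,
                              tube = nanotube(),
                              dim_ranges = list(edge_a = c(4.5, 5),
                                                edge_b = c(5, 6.5),
                                                thickness = c(3.5, 4.5)),
                              cutoff = 0.009,
                              seed = 42L,
                              stop_after_failures = 10000L,
                              n_axial_samples = 100L) {
  if (n_tubes < 1) {
    stop("invalid parameter: n_tubes must be >= 1", call. = FALSE)
  }
  diam <- vector("list", n_tubes)
  ext <- vector("list", n_tubes)
  cov <- numeric(n_tubes)
  npro <- 0L
  for (i in seq_len(n_tubes)) {
    st <- run_rsa(tube, seed = seed + i, dim_ranges = dim_ranges,
                  cutoff = cutoff, stop_after_failures = stop_after_failures)
    diam[[i]] <- projected_diameter_profile(st, n_axial_samples)
    ext[[i]] <- st$placements$radial_extent_nm
    cov[i] <- st$coverage_fraction
    npro <- npro + nrow(st$placements)
  }
  diam <- unlist(diam)
  ext <- unlist(ext)
  structure(list(
    mean_diameter = mean(diam),
    sd_diameter = stats::sd(diam),
    mean_thickness = mean(ext),
    sd_thickness = stats::sd(ext),
    coverage_fraction = mean(cov),
    n_tubes = n_tubes,
    n_proteins = npro,
    seed = seed
  ), class = "coated_tube_stats")
}

#' @export
print.coated_tube_stats <- function(x, ...) {
  cat(sprintf("Coated-tube ensemble (%d tubes, %d proteins, seed %d)\n",
              x$n_tubes, x$n_proteins, x$seed))
  cat(sprintf("  projected diameter: %.1f +/- %.1f nm\n",
              x$mean_diameter, x$sd_diameter))
  cat(sprintf("  layer thickness:    %.2f +/- %.2f nm\n",
              x$mean_thickness, x$sd_thickness))
  cat(sprintf("  surface coverage:   %.3f\n", x$coverage_fraction))
  invisible(x)
}
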