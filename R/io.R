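#' Write a voltammogram to CSV
#'
#' Columns `potential_mV,current_nA,segment`; numbers are serialised with six
#' significant digits so repeated write/read/write cycles are byte-stable.
#'
#' @param v A `voltammogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voltammogram_csv <- function(v, path) {
  stopifnot(is.data.frame(v))
  out <- data.frame(
    potential_mV = formatC(v$potential_mV, format = "g", digits = 6),
    current_nA = formatC(v$current_nA, format = "g", digits = 6),
    segment = v$segment,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voltammogram from CSV
#'
#' Expects the header `potential_mV,current_nA,segment` and validates the
#' sweep invariants: potentials within the sweep range and each segment
#' monotone (forward non-decreasing, reverse non-increasing).
#'
#' @param path CSV path.
#' @param scan_rate Scan rate to attach, mV/s (not stored in the CSV).
#' @param potential_range Allowed sweep limits, mV.
#' @return A `voltammogram` data frame.
#' @export
read_voltammogram_csv <- function(path, scan_rate = 20,
                                  potential_range = c(-600, 300)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("potential_mV", "current_nA", "segment")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0L) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(d$potential_mV) || !is.numeric(d$current_nA)) {
    stop("format error: potential_mV and current_nA must be numeric",
         call. = FALSE)
  }
  if (any(d$potential_mV < potential_range[1] - 1e-9) ||
      any(d$potential_mV > potential_range[2] + 1e-9)) {
    stop("validation error: potentials outside the sweep range", call. = FALSE)
  }
  for (seg in unique(d$segment)) {
    pot <- d$potential_mV[d$segment == seg]
    dp <- diff(pot)
    if (seg == "forward" && any(dp < 0)) {
      stop("validation error: forward segment not monotone non-decreasing",
           call. = FALSE)
    }
    if (seg == "reverse" && any(dp > 0)) {
      stop("validation error: reverse segment not monotone non-increasing",
           call. = FALSE)
    }
  }
  structure(d, scan_rate_mV_s = scan_rate,
            class = c("voltammogram", "data.frame"))
}

#' Read a geometry/energy configuration file
#'
#' YAML or JSON (by extension) with the structure
#' `protein: {edge_a, edge_b, thickness}`, `tube: {diameter, length}`,
#' `cutoff`, and optionally `alpha_J_per_mol_A2`.
#'
#' @param path Config path (`.yaml`/`.yml` or `.json`).
#' @return List with `protein` ([protein_prism()]), `tube` ([nanotube()]),
#'   `cutoff`, and `model` ([hydrophobic_model()]).
#' @export
read_geometry_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("format error: config must be .yaml, .yml or .json", call. = FALSE)
  )
  protein <- do.call(protein_prism, as.list(raw$protein))
  tube <- do.call(nanotube, as.list(raw$tube))
  cutoff <- if (is.null(raw$cutoff)) 0.009 else raw$cutoff
  alpha <- if (is.null(raw$alpha_J_per_mol_A2)) -104.5 else raw$alpha_J_per_mol_A2
  list(protein = protein, tube = tube, cutoff = cutoff,
       model = hydrophobic_model(alpha))
}

#' Write a results list as JSON
#'
#' Serialises a (possibly nested) list of scalars/vectors with six
#' significant digits and unboxed scalars; stochastic results should carry
#' their `seed` element so every artifact records how it was produced.
#'
#' @param x List to serialise (S3 class attributes are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(x, path) {
  x <- rapply(unclass(x), function(v) {
    if (is.double(v)) signif(v, 6) else v
  }, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write RSA placements as CSV
#'
#' @param state An `adsorption_state`, or list of them (tube ids follow the
#'   list order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements_csv <- function(state, path) {
  if (inherits(state, "adsorption_state")) state <- list(state)
  tbl <- do.call(rbind, lapply(seq_along(state), function(i) {
    p <- state[[i]]$placements
    data.frame(tube_id = i, z_nm = p$z_nm, s_nm = p$s_nm,
               orientation_id = p$mode,
               radial_extent_nm = p$radial_extent_nm,
               stringsAsFactors = FALSE)
  }))
  num <- vapply(tbl, is.double, logical(1))
  tbl[num] <- lapply(tbl[num], function(v) formatC(v, format = "g", digits = 6))
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
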