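#' Triangular-prism protein model
#'
#' Crystallographic studies describe cytochrome P450 as roughly a triangular
#' prism of 4.5--5 nm x 5--6.5 nm with a thickness of 3.5--4.5 nm. The model
#' keeps only these three lengths: `edge_a` (triangular base edge), `edge_b`
#' (prism long edge) and `thickness`.
#'
#' @param edge_a Triangular base edge in nm (default midpoint 4.75).
#' @param edge_b Prism long edge in nm (default midpoint 5.75).
#' @param thickness Prism thickness in nm (default midpoint 4.0).
#' @return An object of class `protein_prism`.
#' @export
#' @examples
#' protein_prism(5, 6.5, 4)
protein_prism <- function(edge_a = 4.75, edge_b = 5.75, thickness = 4.0) {
  if (!all(is.finite(c(edge_a, edge_b, thickness))) ||
      any(c(edge_a, edge_b, thickness) <= 0)) {
    stop("invalid parameter: all protein dimensions must be strictly positive",
         call. = FALSE)
  }
  if (edge_a > edge_b) {
    stop("invalid parameter: edge_a must not exceed edge_b", call. = FALSE)
  }
  if (thickness > edge_a) {
    stop("invalid parameter: thickness must not exceed edge_a", call. = FALSE)
  }
  structure(list(edge_a = edge_a, edge_b = edge_b, thickness = thickness),
            class = "protein_prism")
}

#' Carbon nanotube model
#'
#' A straight cylinder; the multi-walled carbon nanotubes used for electrode
#' nanostructuring are about 10 nm in diameter and 1--2 um long.
#'
#' @param diameter Tube diameter in nm.
#' @param length Tube length in nm.
#' @return An object of class `nanotube`.
#' @export
nanotube <- function(diameter = 10, length = 1000) {
  if (!is.finite(diameter) || diameter <= 0) {
    stop("invalid parameter: diameter must be positive", call. = FALSE)
  }
  if (!is.finite(length) || length <= 0) {
    stop("invalid parameter: length must be positive", call. = FALSE)
  }
  structure(list(diameter = diameter, length = length), class = "nanotube")
}

#' Contact area of a flat face tangent to a cylinder
#'
#' A flat protein face resting on a cylindrical tube of radius `r` touches it
#' along a line; the gap g(x) = r - sqrt(r^2 - x^2) grows with the transverse
#' offset x. Surface patches closer than a `cutoff` gap are counted as in
#' contact. For cutoff << r the strip half-width solves g(x) = cutoff, giving
#' the small-gap approximation w = 2*sqrt(2*r*cutoff), so the contact area is
#' w times the face length along the tube axis.
#'
#' @param face_length Length of the contacting face along the tube axis, nm.
#' @param tube_radius Cylinder radius, nm.
#' @param cutoff Gap distance below which surfaces count as in contact, nm.
#' @return Contact area in Angstrom^2 (1 nm^2 = 100 A^2).
#' @export
#' @examples
#' contact_strip_area(5, 5, 0.0084) # ~290 A^2
contact_strip_area <- function(face_length, tube_radius, cutoff) {
  if (any(c(face_length, tube_radius, cutoff) < 0) ||
      !all(is.finite(c(face_length, tube_radius, cutoff)))) {
    stop("invalid parameter: arguments must be non-negative and finite",
         call. = FALSE)
  }
  if (cutoff > tube_radius) {
    stop("invalid parameter: cutoff must not exceed the tube radius",
         call. = FALSE)
  }
  w <- 2 * sqrt(2 * tube_radius * cutoff)
  100 * w * face_length
}

# Internal: per-mode orientation quantities as plain vectors (hot path for the
# RSA sampler; make_orientation_set() wraps this into a data frame).
# Effective contact face lengths: the lateral and triangular faces are flat
# faces (full length in contact); edge and corner modes touch along a line
# whose effective length is halved by the adjoining-face tilt.
.orientation_tbl <- function(edge_a, edge_b, thickness, tube_radius, cutoff) {
  face_len <- c(edge_b, thickness, edge_b / 2, edge_a / 2, thickness / 2)
  list(
    mode = c("lateral", "tri_face", "long_edge", "short_edge", "corner"),
    face_length = face_len,
    contact_area = contact_strip_area(1, tube_radius, cutoff) * face_len,
    radial_extent = c(thickness, edge_b, edge_a, edge_b, edge_b),
    footprint_axial = c(edge_b, thickness, edge_b, edge_a, thickness),
    footprint_arc = c(edge_a, edge_a, thickness, thickness, thickness)
  )
}

#' Attachment orientation set for a prism on a nanotube
#'
#' Enumerates five attachment modes: the preferred lateral (largest) face
#' down, triangular face down, long edge down, short edge down, and a tilted
#' corner contact. Each mode carries its hydrophobic contact area (from
#' [contact_strip_area()] with that mode's contacting face length), the
#' radial extent (how far the adsorbed protein protrudes above the tube
#' surface) and its footprint on the unrolled tube surface.
#'
#' The default cutoff of 0.009 nm is calibrated so that the lateral-face
#' contact area of the midpoint protein (4.75 x 5.75 x 4.0 nm) on a 10 nm
#' tube falls in the 272--378 A^2 range estimated for the P450--nanotube
#' interaction.
#'
#' @param protein A [protein_prism()].
#' @param tube A [nanotube()].
#' @param cutoff Contact gap cutoff in nm.
#' @return A data frame with one row per mode and columns `mode`,
#'   `face_length_nm`, `contact_area_A2`, `radial_extent_nm`,
#'   `footprint_axial_nm`, `footprint_arc_nm`.
#' @export
#' @examples
#' make_orientation_set(protein_prism(), nanotube())
make_orientation_set <- function(protein, tube, cutoff = 0.009) {
  stopifnot(inherits(protein, "protein_prism"), inherits(tube, "nanotube"))
  if (!is.finite(cutoff) || cutoff <= 0) {
    stop("invalid parameter: cutoff must be positive", call. = FALSE)
  }
  o <- .orientation_tbl(protein$edge_a, protein$edge_b, protein$thickness,
                        tube$diameter / 2, cutoff)
  data.frame(
    mode = o$mode,
    face_length_nm = o$face_length,
    contact_area_A2 = o$contact_area,
    radial_extent_nm = o$radial_extent,
    footprint_axial_nm = o$footprint_axial,
    footprint_arc_nm = o$footprint_arc,
    stringsAsFactors = FALSE
  )
}

#' Rectangle on the unrolled tube surface
#'
#' The cylinder is unrolled into a flat band: `z` is the axial coordinate and
#' `s` the arc-length coordinate, periodic with period pi * diameter.
#'
#' @param z_min,z_max Axial extent, nm.
#' @param s_min,s_max Arc-length extent, nm (may exceed the period; wrapping is
#'   handled by [rects_overlap()]).
#' @return An object of class `surface_rect`.
#' @export
surface_rect <- function(z_min, z_max, s_min, s_max) {
  if (!(z_max > z_min) || !(s_max > s_min)) {
    stop("invalid parameter: rectangle extents must be positive", call. = FALSE)
  }
  structure(list(z_min = z_min, z_max = z_max, s_min = s_min, s_max = s_max),
            class = "surface_rect")
}

#' Do two surface rectangles overlap on the cylinder?
#'
#' Axial overlap is ordinary interval overlap; the arc coordinate wraps with
#' the given period. Rectangles that merely touch along an edge do not count
#' as overlapping.
#'
#' @param a,b [surface_rect()] objects with arc width less than `period`.
#' @param period Circumference pi * diameter, nm.
#' @return Logical.
#' @export
rects_overlap <- function(a, b, period) {
  stopifnot(inherits(a, "surface_rect"), inherits(b, "surface_rect"),
            period > 0)
  wa <- a$s_max - a$s_min
  wb <- b$s_max - b$s_min
  if (wa >= period || wb >= period) {
    stop("invalid parameter: arc width must be less than the period",
         call. = FALSE)
  }
  if (a$z_min >= b$z_max || b$z_min >= a$z_max) return(FALSE)
  dc <- (a$s_min + a$s_max) / 2 - (b$s_min + b$s_max) / 2
  dc <- abs((dc + period / 2) %% period - period / 2)
  dc < (wa + wb) / 2
}
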