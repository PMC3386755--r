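# Independent oracles used across the suite; these deliberately avoid the
# code paths they check.

# Strip contact area by numeric evaluation of the true gap function
# g(x) = r - sqrt(r^2 - x^2): area = face_length * width of {x : g(x) <= cutoff},
# measured on a fine grid, in A^2.
oracle_strip_area <- function(face_length, r, cutoff, n = 2e5) {
  x <- seq(-r, r, length.out = n)
  gap <- r - sqrt(pmax(r^2 - x^2, 0))
  width <- diff(range(x[gap <= cutoff]))
  100 * width * face_length
}

# Periodic rectangle overlap by exhaustively testing the three unrolled
# translates of rectangle a against b (flat, open-interval overlap).
oracle_overlap <- function(a, b, period) {
  flat <- function(lo1, hi1, lo2, hi2) lo1 < hi2 && lo2 < hi1
  if (!flat(a$z_min, a$z_max, b$z_min, b$z_max)) return(FALSE)
  any(vapply(c(-period, 0, period), function(t) {
    flat(a$s_min + t, a$s_max + t, b$s_min, b$s_max)
  }, logical(1)))
}

# O(n^2) replay of an RSA state: every pair of accepted footprints must be
# non-overlapping under the translate oracle.
oracle_state_overlap_free <- function(state) {
  p <- state$placements
  if (nrow(p) < 2) return(TRUE)
  period <- pi * state$tube$diameter
  rects <- lapply(seq_len(nrow(p)), function(i) {
    list(z_min = p$z_nm[i] - p$footprint_axial_nm[i] / 2,
         z_max = p$z_nm[i] + p$footprint_axial_nm[i] / 2,
         s_min = p$s_nm[i] - p$footprint_arc_nm[i] / 2,
         s_max = p$s_nm[i] + p$footprint_arc_nm[i] / 2)
  })
  for (i in seq_len(length(rects) - 1)) {
    for (j in (i + 1):length(rects)) {
      if (oracle_overlap(rects[[i]], rects[[j]], period)) return(FALSE)
    }
  }
  TRUE
}

# Default crystallographic dimension ranges (nm).
default_dim_ranges <- function() {
  list(edge_a = c(4.5, 5), edge_b = c(5, 6.5), thickness = c(3.5, 4.5))
}
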