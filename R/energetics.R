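#' Hydrophobic interaction model
#'
#' Buried-surface-area energetics: each square Angstrom of hydrophobically
#' buried surface contributes a fixed enthalpy. Direct measurements on
#' antibody/antigen complexes give 104.5 J/mol per A^2, attractive, hence the
#' default coefficient alpha = -104.5 J/(mol*A^2).
#'
#' @param alpha Enthalpy per unit buried area, J/(mol*A^2); must be negative.
#' @return An object of class `hydrophobic_model`.
#' @export
hydrophobic_model <- function(alpha = -104.5) {
  if (!is.finite(alpha) || alpha >= 0) {
    stop("invalid parameter: alpha must be negative (attractive)",
         call. = FALSE)
  }
  structure(list(alpha = alpha), class = "hydrophobic_model")
}

#' Hydrophobic enthalpy of a contact
#'
#' The hydrophobic enthalpy is proportional to the contact area:
#' dH_phi = alpha * A_contact. With the default alpha, a 272 A^2 contact
#' (the lower end of the P450--nanotube estimate) gives -28.4 kJ/mol and
#' 378 A^2 gives -39.5 kJ/mol.
#'
#' @param area Contact area in A^2 (vectorised).
#' @param model A [hydrophobic_model()].
#' @return Enthalpy in kJ/mol.
#' @export
#' @examples
#' hydrophobic_enthalpy(c(150, 272, 378))
hydrophobic_enthalpy <- function(area, model = hydrophobic_model()) {
  stopifnot(inherits(model, "hydrophobic_model"))
  if (any(!is.finite(area)) || any(area < 0)) {
    stop("invalid parameter: area must be non-negative", call. = FALSE)
  }
  model$alpha * area / 1000
}

#' Free-energy terms of protein--surface complex formation
#'
#' Container for the decomposition
#' dG = dH_phi + dH_el - T*(dS_cf + dS_tr + dS_id):
#' hydrophobic enthalpy, Van der Waals enthalpy, and conformational,
#' translational/rotational and water-stabilisation entropies. Only the
#' hydrophobic term is quantified by the adsorption model; the others default
#' to zero and exist so the full decomposition is representable.
#'
#' @param dH_phi,dH_el Enthalpies, kJ/mol.
#' @param dS_cf,dS_tr,dS_id Entropies, kJ/(mol*K).
#' @param T Temperature, K.
#' @return An object of class `energy_terms`.
#' @export
energy_terms <- function(dH_phi = 0, dH_el = 0, dS_cf = 0, dS_tr = 0,
                         dS_id = 0, T = 298.15) {
  if (!is.finite(T) || T <= 0) {
    stop("invalid parameter: temperature must be positive", call. = FALSE)
  }
  structure(list(dH_phi = dH_phi, dH_el = dH_el, dS_cf = dS_cf,
                 dS_tr = dS_tr, dS_id = dS_id, T = T),
            class = "energy_terms")
}

#' Gibbs free energy of complex formation
#'
#' @param terms An [energy_terms()] object.
#' @return dG in kJ/mol.
#' @export
#' @examples
#' gibbs_free_energy(energy_terms(dH_phi = -28.4))
gibbs_free_energy <- function(terms) {
  stopifnot(inherits(terms, "energy_terms"))
  terms$dH_phi + terms$dH_el -
    terms$T * (terms$dS_cf + terms$dS_tr + terms$dS_id)
}

#' Attachment probabilities over orientation modes
#'
#' The probability of attachment in a given orientation is taken directly
#' proportional to that orientation's hydrophobic contact area (the default).
#' A Boltzmann alternative, p_i proportional to exp(-dG_i / RT) with
#' dG_i the hydrophobic enthalpy of the contact, is available via
#' `weighting = "boltzmann"`.
#'
#' @param orientations Data frame from [make_orientation_set()] (or any data
#'   frame with a `contact_area_A2` column), or a bare numeric vector of
#'   contact areas in A^2.
#' @param weighting `"area"` (default) or `"boltzmann"`.
#' @param model A [hydrophobic_model()] (Boltzmann mode only).
#' @param temperature Temperature in K (Boltzmann mode only).
#' @return Numeric probability vector summing to 1.
#' @export
#' @examples
#' orientation_probabilities(c(272, 378))
orientation_probabilities <- function(orientations, weighting = c("area", "boltzmann"),
                                      model = hydrophobic_model(),
                                      temperature = 298.15) {
  weighting <- match.arg(weighting)
  areas <- if (is.data.frame(orientations)) {
    orientations$contact_area_A2
  } else {
    as.numeric(orientations)
  }
  if (length(areas) == 0L) {
    stop("invalid parameter: need at least one orientation", call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("invalid parameter: contact areas must be positive", call. = FALSE)
  }
  if (weighting == "area") {
    areas / sum(areas)
  } else {
    R <- 8.314462618e-3 # kJ/(mol*K)
    dG <- hydrophobic_enthalpy(areas, model)
    lw <- -dG / (R * temperature)
    w <- exp(lw - max(lw)) # shift for numerical stability
    w / sum(w)
  }
}
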