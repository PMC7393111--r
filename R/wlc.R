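#' Worm-like chain polymer model
#'
#' Container for the polymer parameters used to convert observed extension
#' changes into contour-length changes and to predict the expected
#' contour-length gain upon unfolding of a folded domain.
#'
#' @param persistence_length Persistence length p in nm. Default 0.65 nm,
#'   appropriate for an unfolded polypeptide stretched at tens of pN.
#' @param contour_per_residue Contour length per amino acid in nm. Default
#'   0.36 nm/aa.
#' @param native_end_to_end Distance between the termini of the folded
#'   domain in nm, subtracted when predicting the contour-length change of
#'   unfolding. Default 1.6 nm.
#'
#' @return An object of class `polymer_model`.
#' @examples
#' pm <- polymer_model()
#' expected_contour_change(186, pm) # ~65.4 nm for a 186-residue domain
#' @export
polymer_model <- function(persistence_length = 0.65,
                          contour_per_residue = 0.36,
                          native_end_to_end = 1.6) {
  stopifnot(persistence_length > 0, contour_per_residue > 0,
            native_end_to_end > 0)
  structure(list(persistence_length = persistence_length,
                 contour_per_residue = contour_per_residue,
                 native_end_to_end = native_end_to_end),
            class = "polymer_model")
}

#' @export
print.polymer_model <- function(x, ...) {
  cat("Worm-like chain polymer model\n")
  cat(sprintf("  persistence length : %.3g nm\n", x$persistence_length))
  cat(sprintf("  contour per residue: %.3g nm/aa\n", x$contour_per_residue))
  cat(sprintf("  native end-to-end  : %.3g nm\n", x$native_end_to_end))
  invisible(x)
}

#' Default thermal energy (kBT) in pN nm
#'
#' Room-temperature thermal energy, kBT = 4.11 pN nm (about 24.5 C).
#' @export
KBT_ROOM <- 4.11

#' Worm-like chain force at a given relative extension
#'
#' Marko-Siggia interpolation formula
#' F(z) = (kBT/p) \[1/(4(1-z)^2) - 1/4 + z\]
#' with z = x/L the extension as a fraction of contour length. Strictly
#' increasing on \[0, 1) and divergent as z -> 1.
#'
#' @param relative_extension Fractional extension z in \[0, 1). Vectorised.
#' @param model A [polymer_model()].
#' @param thermal_energy kBT in pN nm.
#' @return Force in pN.
#' @export
wlc_force <- function(relative_extension, model = polymer_model(),
                      thermal_energy = KBT_ROOM) {
  z <- relative_extension
  if (any(z < 0 | z >= 1)) {
    stop("relative_extension must lie in [0, 1)")
  }
  (thermal_energy / model$persistence_length) *
    (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Invert the worm-like chain: relative extension at a given force
#'
#' Numerical inverse of [wlc_force()] by bracketed bisection on z; the
#' forward map is strictly monotone so convergence is guaranteed. The
#' bisection runs to an absolute tolerance of 1e-10 in z.
#'
#' @param force Force in pN (>= 0). Vectorised.
#' @inheritParams wlc_force
#' @return Relative extension z in \[0, 1).
#' @export
wlc_relative_extension <- function(force, model = polymer_model(),
                                   thermal_energy = KBT_ROOM) {
  if (any(force < 0)) stop("force must be non-negative")
  vapply(force, function(f) {
    if (f == 0) return(0)
    lo <- 0
    hi <- 1 - 1e-12
    # bisection: wlc_force is increasing, f > 0 guarantees a sign change
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (wlc_force(mid, model, thermal_energy) < f) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Convert an extension change at a rip to a contour-length change
#'
#' At the rupture force F the released chain is stretched to a fraction
#' z(F) of its contour length, so the contour-length change is
#' dL = dx / z(F). Since z < 1, dL always exceeds the raw extension change.
#'
#' @param delta_extension Observed extension change in nm (> 0).
#' @param rip_force Force at which the rip occurred, pN (> 0).
#' @inheritParams wlc_force
#' @return Contour-length change in nm.
#' @export
extension_to_contour_change <- function(delta_extension, rip_force,
                                        model = polymer_model(),
                                        thermal_energy = KBT_ROOM) {
  if (any(delta_extension <= 0)) stop("delta_extension must be positive")
  if (any(rip_force <= 0)) stop("rip_force must be positive")
  z <- wlc_relative_extension(rip_force, model, thermal_energy)
  delta_extension / z
}

#' Expected contour-length change for unfolding an n-residue domain
#'
#' n residues released at 0.36 nm/aa, minus the native end-to-end distance
#' already spanned by the folded domain.
#'
#' @param n_residues Number of residues in the folded domain (>= 1).
#' @param model A [polymer_model()].
#' @return Expected contour-length change in nm.
#' @examples
#' expected_contour_change(186) # 65.36 nm
#' @export
expected_contour_change <- function(n_residues, model = polymer_model()) {
  stopifnot(n_residues >= 1)
  dl <- n_residues * model$contour_per_residue - model$native_end_to_end
  if (any(dl <= 0)) {
    stop("domain too short for the stated native end-to-end distance")
  }
  dl
}
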