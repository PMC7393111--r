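# Published reference estimates for the proOmpA-mDHFR system. These are
# the study conditions the synthetic-data generators emulate and the
# inputs to the headline force-matching calculation; they are replicate
# averages (mean +/- SD), not raw data.

#' Reference translocation rates for proOmpA-mDHFR
#'
#' Replicate-averaged kinetic rates (1/min) from real-time translocation
#' measurements of the proOmpA-mDHFR fusion under three ligand
#' conditions: apo (no ligand), MTX (methotrexate), and M+N
#' (methotrexate + NADPH). Ligands slow roadblock unfolding while the
#' translocation and incapacitation rates stay essentially constant.
#'
#' @return Data frame with columns `condition`, `k_unfold`,
#'   `sd_k_unfold`, `k_transloc`, `sd_k_transloc`, `k_incap`,
#'   `sd_k_incap`, `n_replicates`.
#' @export
mdhfr_translocation_rates <- function() {
  data.frame(
    condition = c("apo", "MTX", "M+N"),
    k_unfold = c(0.0251, 0.0115, 0.00130),
    sd_k_unfold = c(0.00173, 0.000500, 0.000194),
    k_transloc = c(0.245, 0.239, 0.230),
    sd_k_transloc = c(0.00683, 0.00664, 0.0112),
    k_incap = c(0.0658, 0.0729, 0.0547),
    sd_k_incap = c(0.00990, 0.00888, 0.00492),
    n_replicates = c(4L, 3L, 4L)
  )
}

#' Reference barrier parameters for liganded mDHFR
#'
#' Kramers-like landscape parameters from binless maximum-likelihood
#' analysis of mDHFR rupture forces under force ramps, for the MTX and
#' MTX+NADPH (M+N) conditions (the apo protein populates several native
#' states and is not described by a single barrier).
#'
#' @param condition `"MTX"` or `"M+N"`; omit for the full table.
#' @param nu,thermal_energy Conventions under which the parameters are
#'   interpreted.
#' @return For a single condition, a [barrier_params()] object with an
#'   attribute `"sd"` (named SDs); otherwise a data frame.
#' @examples
#' solve_translocon_force(0.0115, mdhfr_barrier_params("MTX")) # ~10.6 pN
#' @export
mdhfr_barrier_params <- function(condition = NULL, nu = 2 / 3,
                                 thermal_energy = KBT_ROOM) {
  tab <- data.frame(
    condition = c("MTX", "M+N"),
    dx_ddagger = c(1.67, 2.29),
    sd_dx_ddagger = c(0.44, 0.16),
    dG_ddagger = c(15.3, 18.0),
    sd_dG_ddagger = c(1.1, 1.2),
    log10_tau0 = c(5.46, 7.28),
    sd_log10_tau0 = c(0.92, 0.47)
  )
  if (is.null(condition)) return(tab)
  row <- tab[tab$condition == condition, ]
  if (nrow(row) != 1) stop("condition must be \"MTX\" or \"M+N\"")
  bp <- barrier_params(row$log10_tau0, row$dx_ddagger, row$dG_ddagger,
                       nu = nu, thermal_energy = thermal_energy)
  attr(bp, "sd") <- c(log10_tau0 = row$sd_log10_tau0,
                      dx_ddagger = row$sd_dx_ddagger,
                      dG_ddagger = row$sd_dG_ddagger)
  bp
}

#' Number of residues in the mDHFR domain
#'
#' Chain length of murine dihydrofolate reductase (PDB 1u70), used to
#' predict the expected contour-length change of complete unfolding
#' (about 65.4 nm with the default polymer model).
#' @export
MDHFR_N_RESIDUES <- 186L
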