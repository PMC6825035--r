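# Enzyme-lattice interaction energies and kinetic parameters.

#' MMP-collagen interaction energy model
#'
#' Energies are in units of kT. A collagenase on an uncleaved (native)
#' molecule feels a single high-affinity well of depth `e_well` at axial
#' index `well_index` and zero elsewhere; on a gelatin molecule (one with at
#' least one cleaved bond) it feels `e_collagenase_gelatin` everywhere, and
#' it may never occupy a site flanking a cleaved bond (an absorbing
#' "forbidden" marker, `Inf`, that never enters arithmetic - such moves are
#' rejected before the Boltzmann test). A gelatinase feels
#' `e_gelatinase_collagen` on native molecules and `e_gelatinase_gelatin`
#' on gelatin, at any axial index.
#'
#' Two cleavage conventions are supported. The default, `"well"`, lets the
#' collagenase cleave while it occupies the well site, severing the bond
#' directly below (between `well_index - 1` and `well_index`): the enzyme
#' that just cleaved sits above the new cut, which produces the emergent
#' C-to-N ratchet of collagenase tracking. The alternative `"site_below"`
#' places cleavage competence on the site below the well
#' (`cleave_index = well_index - 1`) and severs the bond above the occupied
#' site. Both sever the same bond.
#'
#' @param e_well Well depth (kT) at the collagenase high-affinity site.
#' @param well_index Axial index `i` of the well (counted from the C
#'   terminus).
#' @param e_collagenase_gelatin Collagenase-on-gelatin energy (kT).
#' @param e_gelatinase_collagen Gelatinase-on-native-collagen energy (kT).
#' @param e_gelatinase_gelatin Gelatinase-on-gelatin energy (kT).
#' @param cleave_mode `"well"` or `"site_below"` (see Details).
#' @param cleave_index Collagenase cleavage-competent axial index; defaults
#'   to `well_index` for `"well"` and `well_index - 1` for `"site_below"`.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(e_well = -2,
                         well_index = 5L,
                         e_collagenase_gelatin = 0.5,
                         e_gelatinase_collagen = 0,
                         e_gelatinase_gelatin = -0.5,
                         cleave_mode = c("well", "site_below"),
                         cleave_index = NULL) {
  cleave_mode <- match.arg(cleave_mode)
  if (is.null(cleave_index)) {
    cleave_index <- if (cleave_mode == "well") well_index else well_index - 1L
  }
  stopifnot(is.finite(e_well), well_index >= 1L, cleave_index >= 1L)
  structure(list(
    e_well = as.numeric(e_well),
    well_index = as.integer(well_index),
    e_collagenase_gelatin = as.numeric(e_collagenase_gelatin),
    e_collagenase_cleaved = Inf,  # forbidden marker, never used in arithmetic
    e_gelatinase_collagen = as.numeric(e_gelatinase_collagen),
    e_gelatinase_gelatin = as.numeric(e_gelatinase_gelatin),
    cleave_mode = cleave_mode,
    cleave_index = as.integer(cleave_index)
  ), class = "energy_model")
}

#' Map the diffusion coefficient to the step time
#'
#' On a flat energy landscape a vertical trial displaces the enzyme by one
#' site (`site_length`) with probability `p_vertical` per attempt, so the
#' one-dimensional mean-squared displacement per attempt is
#' `p_vertical * site_length^2`. Matching `MSD = 2 D t` gives the seconds of
#' real time represented by one attempted move per enzyme:
#' `dt = p_vertical * site_length^2 / (2 D)`.
#'
#' @param diffusion_coefficient Target axial diffusion coefficient
#'   (nm^2/s).
#' @param site_length Lattice site length (nm).
#' @param p_vertical Probability that a selected enzyme attempts a vertical
#'   move.
#' @return `dt_attempt` in seconds.
#' @export
calibrate_kinetics <- function(diffusion_coefficient, site_length,
                               p_vertical = 0.9) {
  if (!is.finite(site_length) || site_length <= 0) {
    stop("site_length must be positive", call. = FALSE)
  }
  if (!is.finite(diffusion_coefficient) || diffusion_coefficient <= 0) {
    stop("diffusion_coefficient must be positive", call. = FALSE)
  }
  if (p_vertical <= 0 || p_vertical > 1) {
    stop("p_vertical must be in (0, 1]", call. = FALSE)
  }
  p_vertical * site_length^2 / (2 * diffusion_coefficient)
}

#' Kinetic configuration of the Monte Carlo engine
#'
#' Per selected step an enzyme attempts a vertical move (probability
#' `p_vertical`), a horizontal move (`p_horizontal`) or a cleave
#' (`p_cleave_attempt`); the three must sum to 1 and vertical attempts are
#' much more probable than horizontal ones. The real time represented by
#' one attempt, `dt_attempt`, is set from the target diffusion coefficient
#' (see [calibrate_kinetics()]); one engine step advances the clock by
#' `dt_attempt / n_enzymes`. A cleave attempt in a competent state succeeds
#' with probability `cleave_rate * dt_attempt / p_cleave_attempt`, which
#' makes the competent-state waiting time exponential with mean
#' `1 / cleave_rate`.
#'
#' @param p_vertical,p_horizontal,p_cleave_attempt Attempt-type
#'   probabilities (must sum to 1).
#' @param cleave_rate Overall cleavage rate in the competent state (1/s).
#' @param diffusion_coefficient Target surface diffusion coefficient
#'   (nm^2/s). The literature value for MMPs tracking on collagen fibrils
#'   is of order 1 um^2/s; the default is 8e5 nm^2/s.
#' @param site_length Lattice site length (nm) used for the calibration.
#' @param dt_attempt Override the calibrated attempt time (s).
#' @param cleave_enabled Set `FALSE` to disable cleavage (pure diffusion).
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(p_vertical = 0.90,
                            p_horizontal = 0.09,
                            p_cleave_attempt = 0.01,
                            cleave_rate = 0.35,
                            diffusion_coefficient = 8e5,
                            site_length = 13.4,
                            dt_attempt = NULL,
                            cleave_enabled = TRUE) {
  tot <- p_vertical + p_horizontal + p_cleave_attempt
  if (abs(tot - 1) > 1e-9) {
    stop("p_vertical + p_horizontal + p_cleave_attempt must sum to 1",
         call. = FALSE)
  }
  if (is.null(dt_attempt)) {
    dt_attempt <- calibrate_kinetics(diffusion_coefficient, site_length,
                                     p_vertical)
  }
  p_succ <- if (p_cleave_attempt > 0) {
    cleave_rate * dt_attempt / p_cleave_attempt
  } else 0
  if (p_succ > 1) {
    stop(sprintf(paste0(
      "per-attempt cleave probability %.3g exceeds 1; raise ",
      "p_cleave_attempt or lower dt_attempt"), p_succ), call. = FALSE)
  }
  structure(list(
    p_vertical = p_vertical,
    p_horizontal = p_horizontal,
    p_cleave_attempt = p_cleave_attempt,
    cleave_rate = cleave_rate,
    diffusion_coefficient = diffusion_coefficient,
    site_length = site_length,
    dt_attempt = dt_attempt,
    p_cleave_success = p_succ,
    cleave_enabled = isTRUE(cleave_enabled)
  ), class = "kinetics_config")
}

#' Predicted stationary pause fraction at the collagenase well
#'
#' Closed-form Boltzmann prediction for the fraction of steps a single
#' collagenase spends at the well index: surface sites are weighted by
#' `exp(-E)` under the given energy model (Metropolis dynamics with
#' symmetric proposals leave exactly this distribution invariant).
#'
#' @param lattice A `fibril_lattice`.
#' @param energy An [energy_model()].
#' @return Fraction in `[0, 1]`.
#' @export
pause_fraction_boltzmann <- function(lattice, energy = energy_model()) {
  surf <- surface_sites(lattice)
  gel <- lattice$gelatin[lattice$site_chain[surf]]
  i <- lattice$site_i[surf]
  w <- ifelse(gel, exp(-energy$e_collagenase_gelatin),
              ifelse(i == energy$well_index, exp(-energy$e_well), 1))
  sum(w[i == energy$well_index & !gel]) / sum(w)
}

#' Calibrate the collagenase well depth to a target pause fraction
#'
#' Implements the estimation procedure used to set the well energy: the
#' well depth is adjusted until a single collagenase spends the target
#' fraction of simulation steps paused at its characteristic cleave site
#' (single-molecule tracking reports ~18% "class II" pauses). The closed
#' form inverts the Boltzmann fraction directly; `method = "mc"` refines
#' the closed-form value against a finite Monte Carlo run.
#'
#' @param lattice A `fibril_lattice`.
#' @param target Target pause fraction (default 0.18).
#' @param energy Base [energy_model()]; all fields except `e_well` are kept.
#' @param method `"closed_form"` (default) or `"mc"`.
#' @param mc_steps,seed Monte Carlo refinement controls.
#' @return An `energy_model` with the calibrated `e_well`.
#' @export
calibrate_well_energy <- function(lattice, target = 0.18,
                                  energy = energy_model(),
                                  method = c("closed_form", "mc"),
                                  mc_steps = 5e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(target > 0, target < 1)
  surf <- surface_sites(lattice)
  gel <- lattice$gelatin[lattice$site_chain[surf]]
  n_well <- sum(lattice$site_i[surf] == energy$well_index & !gel)
  w_other <- sum(ifelse(gel[lattice$site_i[surf] != energy$well_index],
                        exp(-energy$e_collagenase_gelatin), 1))
  if (n_well == 0) stop("no surface sites at the well index", call. = FALSE)
  w <- target * w_other / (n_well * (1 - target))
  e_well <- -log(w)
  out <- energy
  out$e_well <- e_well
  if (method == "mc") {
    # one secant refinement against a finite-run estimate
    if (!is.null(seed)) set.seed(seed)
    measure <- function(e) {
      en <- out; en$e_well <- e
      st <- place_enzymes(build_like(lattice), 1L, 0L, energy = en,
                          kinetics = kinetics_config(
                            site_length = lattice$geometry$site_length,
                            cleave_enabled = FALSE))
      st <- run_until(st, max_steps = mc_steps)
      pause_fraction(st, 1L, en$well_index)
    }
    f1 <- measure(e_well)
    # adjust in log-weight space where the response is close to linear
    w2 <- exp(-e_well) * target * (1 - f1) / (f1 * (1 - target))
    out$e_well <- -log(w2)
  }
  out
}

# fresh copy of a lattice in its pristine state (same geometry)
build_like <- function(lattice) build_fibril(lattice$geometry)
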