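# Post-processing of tensile trajectories: yield point, toughness,
# bond-length distributions and sliding/stretching classification.

as_curve <- function(curve) {
  if (inherits(curve, "tensile_result")) curve <- curve$curve
  stopifnot(is.data.frame(curve), all(c("strain", "stress_mpa") %in%
                                        names(curve)))
  if (any(diff(curve$strain) <= 0)) {
    stop("strain must be strictly increasing", call. = FALSE)
  }
  curve
}

moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  k <- rep(1 / window, window)
  n <- length(x)
  pad <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  as.numeric(stats::filter(xp, k, sides = 2))[(pad + 1L):(pad + n)]
}

#' Yield point of a stress-strain curve
#'
#' The yield point is the first sample at which the smoothed tangent
#' modulus falls below `fraction` (default 10%) of the initial elastic
#' modulus (the mean smoothed modulus over the first tenth of the curve).
#' Smoothing is a local moving-average of the finite-difference modulus;
#' the raw curve is never modified.
#'
#' @param curve A `tensile_result` or a data frame with `strain` and
#'   `stress_mpa` (at least 10 points, strictly increasing strain).
#' @param fraction Tangent-modulus fraction defining yield.
#' @param window Smoothing window in samples (default ~ n/10).
#' @return A list with `yield_strain`, `yield_stress`, `initial_modulus`.
#' @export
yield_point <- function(curve, fraction = 0.1, window = NULL) {
  cv <- as_curve(curve)
  n <- nrow(cv)
  if (n < 10L) stop("need at least 10 points", call. = FALSE)
  slope <- diff(cv$stress_mpa) / diff(cv$strain)
  if (is.null(window)) window <- max(5L, n %/% 10L)
  sm <- moving_average(slope, window)
  n0 <- max(3L, length(sm) %/% 10L)
  e0 <- mean(sm[seq_len(n0)])
  if (!is.finite(e0) || e0 <= 0) {
    stop("no yield detected: initial modulus is not positive",
         call. = FALSE)
  }
  idx <- which(sm < fraction * e0)
  idx <- idx[idx > n0]
  if (!length(idx)) stop("no yield detected", call. = FALSE)
  k <- idx[1] + 1L  # slope k refers to the interval (k, k+1)
  list(yield_strain = cv$strain[k], yield_stress = cv$stress_mpa[k],
       initial_modulus = e0)
}

#' Toughness (area under the stress-strain curve)
#'
#' Trapezoidal integral of stress over strain on `[0, up_to_strain]`,
#' interpolating the end point; an energy density in MPa (= MJ/m^3).
#'
#' @param curve As in [yield_point()].
#' @param up_to_strain Integration bound; defaults to the full simulated
#'   range.
#' @return Energy density (MPa).
#' @export
toughness <- function(curve, up_to_strain = NULL) {
  cv <- as_curve(curve)
  if (is.null(up_to_strain)) up_to_strain <- max(cv$strain)
  if (up_to_strain < 0 || up_to_strain > max(cv$strain) + 1e-12) {
    stop("up_to_strain outside the curve range", call. = FALSE)
  }
  s <- c(0, cv$strain)
  sig <- c(0, cv$stress_mpa)
  keep <- s <= up_to_strain
  s_end <- approx(s, sig, xout = up_to_strain, rule = 2)$y
  s <- c(s[keep], up_to_strain)
  sig <- c(sig[keep], s_end)
  sum(diff(s) * (head(sig, -1) + tail(sig, -1)) / 2)
}

#' Normalised bond-length distribution
#'
#' @param lengths Numeric vector of intact bond lengths (a frame), or a
#'   `tensile_result` frame index via `frame`.
#' @param bins Number of bins or a vector of breakpoints.
#' @return A list with `mids`, `density`, `counts`, `breaks`; densities
#'   integrate to 1.
#' @export
bond_length_distribution <- function(lengths, bins = 60) {
  if (!length(lengths)) stop("empty frame: no intact bonds", call. = FALSE)
  stopifnot(all(lengths > 0))
  h <- if (length(bins) > 1) {
    graphics::hist(lengths, breaks = bins, plot = FALSE)
  } else {
    graphics::hist(lengths, breaks = as.integer(bins), plot = FALSE)
  }
  list(mids = h$mids, density = h$density, counts = h$counts,
       breaks = h$breaks)
}

#' Location of the dominant low-length (sliding) mode
#'
#' Kernel-density mode of the bond-length sample restricted to lengths
#' below the stiffened-regime onset, i.e. the sliding population peak.
#'
#' @param lengths Bond lengths (Angstrom).
#' @param upper Restrict the search below this length (default: no limit).
#' @return Peak location (Angstrom).
#' @export
sliding_peak <- function(lengths, upper = Inf) {
  x <- lengths[lengths < upper]
  if (!length(x)) stop("no bonds below `upper`", call. = FALSE)
  d <- density(x)
  d$x[which.max(d$y)]
}

#' Sliding/stretching classification threshold
#'
#' When the distribution is bimodal, the threshold is the kernel-density
#' minimum between the two largest modes; otherwise it falls back to the
#' midpoint between `r0` and the location of the stretched peak (or
#' `r0 + 2` Angstrom when no second mode exists).
#'
#' @param lengths Bond lengths.
#' @param r0 Equilibrium bond length.
#' @return Threshold length.
#' @export
sliding_threshold <- function(lengths, r0 = 14.7) {
  d <- density(lengths)
  y <- d$y
  n <- length(y)
  is_max <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  is_max <- is_max[order(y[is_max], decreasing = TRUE)]
  if (length(is_max) >= 2) {
    two <- sort(is_max[1:2])
    between <- two[1]:two[2]
    return(d$x[between[which.min(y[between])]])
  }
  upper_peak <- d$x[is_max[1]]
  if (upper_peak > r0 + 1) (r0 + upper_peak) / 2 else r0 + 2
}

#' Classify bonds into sliding and stretching populations
#'
#' Sliding bonds have length below the threshold (close to the undeformed
#' length, i.e. chains slipping past each other); stretching bonds are at
#' or above it (covalently loaded). The two fractions sum to 1.
#'
#' @param lengths Bond lengths.
#' @param threshold Classification threshold (> 0).
#' @return Named numeric vector `c(sliding_fraction, stretching_fraction)`.
#' @export
classify_bonds <- function(lengths, threshold) {
  stopifnot(threshold > 0)
  if (!length(lengths)) stop("empty frame: no intact bonds", call. = FALSE)
  sliding <- mean(lengths < threshold)
  c(sliding_fraction = sliding, stretching_fraction = 1 - sliding)
}

#' Bond-length distribution as a function of strain
#'
#' Assembles the per-frame bond-length histograms of a tensile run into a
#' contour-ready grid; each strain row is normalised to sum to 1.
#'
#' @param frames A `tensile_result`, or a list with `bond_frames` (list of
#'   length vectors) and `bond_frame_strain`.
#' @param bins Number of bins (shared breaks across frames).
#' @return A list with `strain`, `mids`, and matrix `probability`
#'   (`length(strain)` x `length(mids)`, rows summing to 1).
#' @export
distribution_vs_strain <- function(frames, bins = 60) {
  if (inherits(frames, "tensile_result")) {
    frames <- list(bond_frames = frames$bond_frames,
                   bond_frame_strain = frames$bond_frame_strain)
  }
  bl <- frames$bond_frames
  if (length(bl) < 2) stop("need at least 2 frames", call. = FALSE)
  rng <- range(unlist(lapply(bl, range)))
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1L)
  prob <- t(vapply(bl, function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }, numeric(bins)))
  list(strain = frames$bond_frame_strain,
       mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
       probability = prob)
}
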