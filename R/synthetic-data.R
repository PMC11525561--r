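# Derive a stream sub-seed from a master seed; keeps all randomness keyed
# to one integer while letting generators re-seed independently.
sub_seed <- function(seed, stream) {
  (as.integer(seed) + 1000003L * as.integer(stream)) %% .Machine$integer.max
}

#' Generate synthetic residue-pair distance trajectories
#'
#' Each replicate is an exactly discretized Ornstein-Uhlenbeck process:
#' `d[t+dt] = mu + (d[t] - mu) * a + sd * sqrt(1 - a^2) * z`, with
#' `a = exp(-dt/tau)` and `d[0] ~ N(mu, sd)`, i.e. a stationary Gaussian
#' series with mean `mean_distance`, SD `stationary_sd` and correlation
#' time `correlation_time` -- the minimal stationary autocorrelated model
#' of a fluctuating inter-residue distance. The series is realized as two
#' pseudo-residues (CYS 50 and ASN 65) whose CA atoms sit at the origin and
#' at (d, 0, 0), so the whole structure-to-distance pipeline can run on it;
#' embedding on the x-axis leaves tests free to apply arbitrary rigid-body
#' transforms.
#'
#' @param mean_distance stationary mean (nm; default 2.0, a plausible
#'   CA-CA separation for the membrane-binding-domain pair).
#' @param stationary_sd stationary SD (nm; default 0.1). Zero gives a
#'   constant series.
#' @param correlation_time OU correlation time (ns; default 5).
#' @param n_frames frames per replicate (>= 10; default 200).
#' @param dt frame spacing (ns; default 1, so the default replicate spans
#'   200 ns, the replicate production-run length).
#' @param n_replicates number of replicates (default 5, the replicate-run
#'   protocol).
#' @param seed master integer seed.
#' @return list of [trajectory_frames] objects with an attribute `truth`
#'   (the generating parameters).
#' @export
gen_trajectory <- function(mean_distance = 2.0, stationary_sd = 0.1,
                           correlation_time = 5, n_frames = 200L, dt = 1,
                           n_replicates = 5L, seed = 1L) {
  stopifnot(mean_distance > 0, stationary_sd >= 0, correlation_time > 0,
            n_frames >= 10L, dt > 0, n_replicates >= 1L)
  a <- exp(-dt / correlation_time)
  atoms <- data.frame(chain = "A", resno = c(50L, 65L),
                      resname = c("CYS", "ASN"), atom = "CA",
                      stringsAsFactors = FALSE)
  reps <- lapply(seq_len(n_replicates), function(r) {
    d <- with_seed(sub_seed(seed, r), {
      z <- stats::rnorm(n_frames)
      d <- numeric(n_frames)
      d[1L] <- mean_distance + stationary_sd * z[1L]
      for (i in seq_len(n_frames - 1L))
        d[i + 1L] <- mean_distance + (d[i] - mean_distance) * a +
          stationary_sd * sqrt(1 - a^2) * z[i + 1L]
      d
    })
    coords <- array(0, dim = c(n_frames, 2L, 3L))
    coords[, 2L, 1L] <- d * 10  # nm -> Angstrom on the x-axis
    trajectory_frames(atoms, coords, times = (seq_len(n_frames) - 1L) * dt,
                      source_label = sprintf("rep%d", r))
  })
  attr(reps, "truth") <- list(mean_distance = mean_distance,
                              stationary_sd = stationary_sd,
                              correlation_time = correlation_time,
                              n_frames = n_frames, dt = dt,
                              n_replicates = n_replicates, seed = seed)
  reps
}

#' Generate a synthetic Michaelis-Menten plate
#'
#' Well signal = background + slope * v(S) * time + Gaussian noise with SD
#' `noise_sd_fraction * vmax * slope * time`, where v(S) is the
#' Michaelis-Menten rate. Zero-substrate wells carry pure background (plus
#' noise). A noiseless standard-curve block (signal = slope * conc) is
#' included, as are matched background values.
#'
#' @param vmax,km generating kinetic parameters (defaults 8.66 uM/h and
#'   11.59 uM, the control-enzyme acyltransferase values).
#' @param substrate_concs well concentrations (uM); default the
#'   seven-point plate 0, 6.4, 9.6, 14.4, 21.6, 32.5, 50.6.
#' @param noise_sd_fraction Gaussian noise SD as a fraction of the
#'   full-scale signal (default 0.02).
#' @param n_replicates triplicate by default.
#' @param time_h reaction time (h; default 1).
#' @param standard_curve_slope AU per uM (default 40).
#' @param background_mean AU (default 50).
#' @param condition_label condition tag (default "LCAT").
#' @param seed master integer seed.
#' @return list with `plate` (long data.frame as consumed by
#'   [signal_to_rate()]), `standard_curve` (conc/signal block) and `truth`.
#' @export
gen_mm_assay <- function(vmax = 8.66, km = 11.59,
                         substrate_concs = c(0, 6.4, 9.6, 14.4, 21.6, 32.5, 50.6),
                         noise_sd_fraction = 0.02, n_replicates = 3L,
                         time_h = 1, standard_curve_slope = 40,
                         background_mean = 50, condition_label = "LCAT",
                         seed = 1L) {
  stopifnot(vmax > 0, km > 0, standard_curve_slope > 0,
            noise_sd_fraction >= 0, time_h > 0, n_replicates >= 1L)
  S <- rep(substrate_concs, times = n_replicates)
  rep_id <- rep(sprintf("rep%d", seq_len(n_replicates)),
                each = length(substrate_concs))
  v <- vmax * S / (km + S)
  noise_sd <- noise_sd_fraction * vmax * standard_curve_slope * time_h
  noise <- with_seed(sub_seed(seed, 101L),
                     stats::rnorm(length(S), sd = noise_sd))
  if (noise_sd == 0) noise <- numeric(length(S))
  plate <- data.frame(
    condition_label = condition_label, replicate_id = rep_id,
    substrate_conc = S,
    signal = background_mean + standard_curve_slope * v * time_h + noise,
    background_signal = background_mean, time_h = time_h,
    stringsAsFactors = FALSE)
  std <- data.frame(conc = substrate_concs,
                    signal = standard_curve_slope * substrate_concs)
  list(plate = plate, standard_curve = std,
       truth = list(vmax = vmax, km = km, substrate_concs = substrate_concs,
                    noise_sd_fraction = noise_sd_fraction,
                    n_replicates = n_replicates, time_h = time_h,
                    standard_curve_slope = standard_curve_slope,
                    background_mean = background_mean, seed = seed))
}

#' Generate synthetic dose-response data
#'
#' 4PL responses (percent of control) at the supplied concentrations plus
#' Gaussian noise.
#'
#' @param ec50,top,bottom,hill generating curve (defaults 0.1 uM, 250, 100,
#'   1: an activator reaching 2.5x control with half-maximal activation at
#'   100 nM, the potency scale of the measured activators).
#' @param concs dose levels (uM); default the five-point design
#'   0.001, 0.01, 0.1, 1, 10.
#' @param noise_sd response noise SD in percent points (default 0).
#' @param n_replicates default 3.
#' @param seed master integer seed.
#' @return list with `responses` (data.frame conc/response/replicate_id)
#'   and `truth`.
#' @export
gen_dose_response <- function(ec50 = 0.1, top = 250, bottom = 100, hill = 1,
                              concs = c(0.001, 0.01, 0.1, 1, 10),
                              noise_sd = 0, n_replicates = 3L, seed = 1L) {
  stopifnot(ec50 > 0, all(concs > 0), noise_sd >= 0, n_replicates >= 1L)
  cc <- rep(concs, times = n_replicates)
  rep_id <- rep(sprintf("rep%d", seq_len(n_replicates)), each = length(concs))
  mu <- bottom + (top - bottom) / (1 + 10^((log10(ec50) - log10(cc)) * hill))
  noise <- if (noise_sd > 0)
    with_seed(sub_seed(seed, 202L), stats::rnorm(length(cc), sd = noise_sd))
  else numeric(length(cc))
  list(responses = data.frame(conc = cc, response = mu + noise,
                              replicate_id = rep_id,
                              stringsAsFactors = FALSE),
       truth = list(ec50 = ec50, top = top, bottom = bottom, hill = hill,
                    concs = concs, noise_sd = noise_sd,
                    n_replicates = n_replicates, seed = seed))
}

#' Generate a synthetic screening library with known filter outcomes
#'
#' Samples compound masses, formal-charge flags and SP/XP docking scores,
#' and computes the expected stage counts of [apply_filters()] by direct
#' enumeration over the sampled flags -- so the filter pipeline can be
#' checked against an oracle that never runs the pipeline itself.
#'
#' @param n library size (>= 1).
#' @param frac_charged fraction carrying a formal charge (default 0.3).
#' @param mass_range uniform mass sampling range in g/mol (default
#'   c(50, 700), deliberately wider than the 100-600 window).
#' @param score_mean,score_sd Gaussian SP docking-score distribution
#'   (defaults -6, 1.5; scores near the -7 cut-off on both sides).
#' @param mass_min,mass_max,score_cutoff filter thresholds used for the
#'   expected counts (defaults 100, 600, -7).
#' @param seed master integer seed.
#' @return list with `library` (data.frame) and `expected_counts`.
#' @export
gen_compound_library <- function(n, frac_charged = 0.3,
                                 mass_range = c(50, 700),
                                 score_mean = -6, score_sd = 1.5,
                                 mass_min = 100, mass_max = 600,
                                 score_cutoff = -7, seed = 1L) {
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1")
  n <- as.integer(n)
  dat <- with_seed(sub_seed(seed, 303L), {
    list(mass = stats::runif(n, mass_range[1L], mass_range[2L]),
         charged = stats::runif(n) < frac_charged,
         sp = stats::rnorm(n, score_mean, score_sd),
         xp_jit = stats::rnorm(n, 0, 0.3))
  })
  lib <- data.frame(
    compound_id = sprintf("CPD%04d", seq_len(n)),
    name = sprintf("compound-%04d", seq_len(n)),
    mass = dat$mass,
    has_charged_group = dat$charged,
    docking_score_sp = dat$sp,
    docking_score_xp = dat$sp + dat$xp_jit,
    stringsAsFactors = FALSE)

  # expected stage counts by direct enumeration over the sampled flags
  ok_charge <- !dat$charged
  ok_mass <- ok_charge & dat$mass >= mass_min & dat$mass <= mass_max
  ok_score <- ok_mass & dat$sp <= score_cutoff
  expected <- c(input = n, after_charge = sum(ok_charge),
                after_mass = sum(ok_mass), after_score = sum(ok_score),
                xp_docked = sum(ok_score), md_candidates = sum(ok_score))
  list(library = lib, expected_counts = expected)
}
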