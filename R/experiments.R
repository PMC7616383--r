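#' Desk-scale experiment configuration
#'
#' The numerical study conditions used throughout the package's experiments:
#' a circular 1540 m/s inclusion in a 1500 m/s water background (density
#' 1010 inside and out when the physics match; 1220 inside when they
#' deliberately do not), probed by 32 co-located sources/receivers on a
#' circle, with a 370 kHz Ricker source and a 700 kHz low-pass applied to
#' observed and predicted data. The grid resolution (0.5 mm spacing; about
#' 8 grid points per centre-frequency wavelength, 4.3 at the pass-band
#' edge) matches the canonical 200 x 200 numerical benchmark; for desk
#' scale the *domain* is halved instead (100 x 100 cells = 50 mm, 25 mm
#' inclusion, 40 mm array), keeping every wavelength-per-cell ratio of the
#' full-size setup while the whole experiment set runs on one CPU in
#' minutes. The loop starts from a mean-field Gaussian prior with mean
#' 1480 m/s and variance 4 (m/s)^2 and runs 2 full epochs over the sources
#' (one source per iteration, deterministic round-robin). Observed data are
#' generated at a 2x refined time step so the inversion never sees its own
#' exact discretisation.
#'
#' @param grid Grid side length in cells (default 100).
#' @param dx Grid spacing in m (default 0.5 mm).
#' @param n_sources Elements on the transducer circle (default 32).
#' @param epochs Full passes over the sources (default 2).
#' @param sponge_width Absorbing sponge width in cells (default 40).
#' @return A named list of class `experiment_config`.
#' @export
desk_config <- function(grid = 100L, dx = 0.5e-3, n_sources = 32L,
                        epochs = 2L, sponge_width = 40L) {
  centre <- c((grid - 1) / 2 * dx, (grid - 1) / 2 * dx)
  extent <- (grid - 1) * dx
  structure(list(
    grid = as.integer(grid), dx = dx, centre = centre,
    background_speed = 1500, inclusion_speed = 1540,
    inclusion_diameter = 0.5 * extent + dx,
    background_density = 1010, mismatch_density = 1220,
    array_n = as.integer(n_sources), array_diameter = 0.8 * extent + dx,
    f0 = 370e3, dt = 0.05e-6, nt = 700L,
    cutoff = 700e3, cutoff_skip = 1e6,
    prior_mu = 1480, prior_var = 4, skip_prior_mu = 1400,
    epochs = as.integer(epochs), batch_size = 1L,
    step_frac = 0.01, clip = c(1300, 1800),
    sponge = sponge_spec(sponge_width),
    corruption = corruption_spec(fraction = 4 / n_sources, offset = 2e-3),
    fine_factor = 2L, grid_shift = 0, scheme = "nearest"
  ), class = "experiment_config")
}

exp_phantom_spec <- function(config, mismatch = FALSE) {
  phantom_spec(c(config$grid, config$grid), config$dx,
               background_speed = config$background_speed,
               background_density = config$background_density,
               inclusions = list(circle_inclusion(
                 config$centre, config$inclusion_diameter,
                 speed = config$inclusion_speed,
                 density = if (mismatch) config$mismatch_density
                           else config$background_density)))
}

exp_geometry <- function(config) {
  circular_array(config$array_n, config$array_diameter, config$centre)
}

exp_wavelet <- function(config) ricker_wavelet(config$f0, config$dt)

#' Generate the observed data for a named experiment condition
#'
#' @param config An [desk_config()] list.
#' @param condition One of `"matched"`, `"mismatched"`, `"corrupted"`.
#' @param seed Seed controlling the corruption draw (ignored otherwise).
#' @return List of [shot_gather()]s; attribute `"corrupted"` lists affected
#'   sources for the corrupted condition.
#' @export
experiment_observed <- function(config, condition = c("matched", "mismatched",
                                                      "corrupted"),
                                seed = 1L) {
  condition <- match.arg(condition)
  geom <- exp_geometry(config)
  wv <- exp_wavelet(config)
  mismatch <- condition == "mismatched"
  spec <- exp_phantom_spec(config, mismatch = mismatch)
  gen_geom <- geom
  corrupted <- integer(0)
  if (condition == "corrupted") {
    gen_geom <- corrupt_geometry(geom, config$corruption, seed = seed + 1000L)
    corrupted <- gen_geom$meta$corrupted
  }
  obs <- generate_observed(spec, gen_geom, wv, matched = !mismatch,
                           nt = config$nt, fine_factor = config$fine_factor,
                           grid_shift = config$grid_shift,
                           sponge = config$sponge, scheme = config$scheme)
  attr(obs, "corrupted") <- corrupted
  obs
}

exp_invert <- function(config, observed, seed, prior_mu = config$prior_mu,
                       cutoff = config$cutoff, deterministic = FALSE,
                       store_trajectory = FALSE, alpha = NULL) {
  init <- init_from_prior(prior_spec(prior_mu, config$prior_var),
                          c(config$grid, config$grid))
  cfg <- inversion_config(iterations = config$epochs * config$array_n,
                          batch_size = config$batch_size, cutoff = cutoff,
                          step_frac = config$step_frac, alpha = alpha,
                          clip = config$clip,
                          deterministic = deterministic,
                          sponge = config$sponge, scheme = config$scheme,
                          store_trajectory = store_trajectory)
  run_inversion(observed, init, exp_geometry(config), exp_wavelet(config),
                cfg, dx = config$dx, seed = seed)
}

#' Run a named synthetic experiment
#'
#' Orchestrates simulate -> invert -> QC for one of the canonical
#' uncertainty-monitoring experiments:
#' \describe{
#'   \item{progressive_decoding}{Matched-physics inversion; the mean-variance
#'     trace rises early, falls, and settles below its peak as the image
#'     sharpens.}
#'   \item{cycle_skip}{The inversion is started half a period out of phase
#'     (erroneous 1400 m/s prior mean) with a 1 MHz pass-band that removes
#'     the low-frequency safety net; the variance is higher and still
#'     rising at the end.}
#'   \item{physics_mismatch}{Observed data carry a density contrast the
#'     constant-density inversion cannot represent; variance is elevated,
#'     concentrating in a ring at the inclusion boundary.}
#'   \item{artefact}{A contiguous arc of sources is displaced by 2 mm when
#'     generating the data only; the variance image develops a localised
#'     hot region near the corrupted sector.}
#' }
#'
#' @param name Experiment name.
#' @param seed Integer seed (sampling stream; also the corruption draw).
#' @param config An [desk_config()].
#' @param observed Optional pre-generated observed data (from
#'   [experiment_observed()]) to reuse across runs.
#' @param reference Optional reference `inversion_report` from a matched run.
#'   Comparison experiments (`cycle_skip`, `physics_mismatch`, `artefact`)
#'   reuse the reference run's step size `alpha` so that the compared runs
#'   share identical algorithm settings and differ only through the data;
#'   they also report the reference values they are compared against.
#' @return A list of class `experiment_summary`; always contains `name`,
#'   `seed`, `report`, `trend`; comparison experiments add the fields they
#'   need (see details in the package vignette).
#' @export
run_experiment <- function(name = c("progressive_decoding", "cycle_skip",
                                    "physics_mismatch", "artefact"),
                           seed = 1L, config = desk_config(),
                           observed = NULL, reference = NULL) {
  name <- match.arg(name)
  out <- list(name = name, seed = seed, config = config)
  regions <- phantom_regions(exp_phantom_spec(config), config$array_diameter)
  alpha_ref <- if (!is.null(reference)) reference$alpha else NULL
  if (name == "progressive_decoding") {
    if (is.null(observed)) observed <- experiment_observed(config, "matched")
    rep_ <- exp_invert(config, observed, seed)
    out$report <- rep_
    out$trend <- variance_trend(rep_)
    out$interior_median <- stats::median(rep_$mu[regions$interior])
    out$background_median <- stats::median(rep_$mu[regions$background])
    out$n_interior <- sum(regions$interior)
    out$n_background <- sum(regions$background)
  } else if (name == "cycle_skip") {
    if (is.null(observed)) observed <- experiment_observed(config, "matched")
    rep_ <- exp_invert(config, observed, seed,
                       prior_mu = config$skip_prior_mu,
                       cutoff = config$cutoff_skip, alpha = alpha_ref)
    out$report <- rep_
    out$trend <- variance_trend(rep_)
    if (!is.null(reference)) {
      out$reference_final <- reference$mean_variance[reference$iterations]
      out$failure <- flag_failure(rep_, reference = out$reference_final)
    } else {
      out$failure <- flag_failure(rep_)
    }
  } else if (name == "physics_mismatch") {
    if (is.null(observed)) observed <- experiment_observed(config, "mismatched")
    rep_ <- exp_invert(config, observed, seed, alpha = alpha_ref)
    out$report <- rep_
    out$trend <- variance_trend(rep_)
    e1 <- config$array_n  # end of the first source epoch
    out$epoch1_mean_variance <- rep_$mean_variance[e1]
    if (!is.null(reference))
      out$reference_epoch1_mean_variance <- reference$mean_variance[e1]
    s2 <- rep_$sigma2
    out$boundary_variance <- mean(s2[regions$boundary])
    out$offboundary_variance <- mean(s2[regions$interior | regions$background])
  } else if (name == "artefact") {
    if (is.null(observed)) observed <- experiment_observed(config, "corrupted",
                                                          seed = seed)
    rep_ <- exp_invert(config, observed, seed, alpha = alpha_ref)
    out$report <- rep_
    out$trend <- variance_trend(rep_)
    out$corrupted_sources <- attr(observed, "corrupted")
    out$mask <- artefact_mask(rep_$sigma2)
    out$max_block_variance <- max_block_mean(rep_$sigma2)
  }
  structure(out, class = "experiment_summary")
}

max_block_mean <- function(v, block = 5) {
  nbz <- floor(nrow(v) / block); nbx <- floor(ncol(v) / block)
  mx <- -Inf
  for (i in seq_len(nbz)) for (j in seq_len(nbx)) {
    mx <- max(mx, mean(v[((i - 1) * block + 1):(i * block),
                         ((j - 1) * block + 1):(j * block)]))
  }
  mx
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary> %s (seed %d): %d iterations, final mean variance %.4g\n",
              x$name, x$seed, x$report$iterations, x$trend$final))
  invisible(x)
}

#' Sector mask near given array sources
#'
#' Pixels within `width` metres of the chord region between the array centre
#' and the listed source positions — used to check that an artefact mask
#' overlaps the corrupted sector of the array.
#'
#' @param config An [desk_config()].
#' @param sources Integer indices of array elements.
#' @param frac Radial fraction of the array radius included (default 1).
#' @return Logical matrix on the model grid.
#' @export
sector_mask <- function(config, sources, frac = 1) {
  geom <- exp_geometry(config)
  nz <- config$grid; nx <- config$grid
  z <- (seq_len(nz) - 1) * config$dx
  x <- (seq_len(nx) - 1) * config$dx
  ctr <- config$centre
  ang_src <- atan2(geom$sources[sources, 1] - ctr[1],
                   geom$sources[sources, 2] - ctr[2])
  zz <- matrix(z, nz, nx)
  xx <- matrix(x, nz, nx, byrow = TRUE)
  ang <- atan2(zz - ctr[1], xx - ctr[2])
  rad <- sqrt((zz - ctr[1])^2 + (xx - ctr[2])^2)
  wrap <- function(a) atan2(sin(a), cos(a))
  dmin <- Reduce(pmin, lapply(ang_src, function(a) abs(wrap(ang - a))))
  gap <- 2 * pi / config$array_n
  dmin <= 1.5 * gap & rad <= frac * config$array_diameter / 2
}
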