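#' Phantom specification
#'
#' Describes a synthetic imaging target: a uniform background with circular
#' inclusions, each carrying its own sound speed and density. The default
#' geometry of `circle_inclusion()` follows the standard numerical ultrasound
#' tomography benchmark: a 50 mm circle of 1540 m/s in a 1500 m/s water-like
#' background.
#'
#' @param grid_shape Integer `(nz, nx)`.
#' @param dx Grid spacing (m).
#' @param background_speed Background sound speed (m/s).
#' @param background_density Background density (phantom units, e.g. 1010).
#' @param inclusions List of inclusions from [circle_inclusion()].
#' @param origin Physical coordinate of grid cell `(1, 1)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, dx, background_speed = 1500,
                         background_density = 1010, inclusions = list(),
                         origin = c(0, 0)) {
  if (background_speed <= 0 || background_density <= 0)
    stop("speeds and densities must be positive")
  structure(list(grid_shape = as.integer(grid_shape), dx = dx,
                 background_speed = background_speed,
                 background_density = background_density,
                 inclusions = inclusions, origin = as.numeric(origin)),
            class = "phantom_spec")
}

#' Circular inclusion for a phantom
#'
#' @param centre `(z, x)` centre (m).
#' @param diameter Diameter (m).
#' @param speed Sound speed inside the circle (m/s).
#' @param density Density inside the circle (phantom units).
#' @return A list describing the inclusion.
#' @export
circle_inclusion <- function(centre, diameter = 50e-3, speed = 1540,
                             density = 1010) {
  if (speed <= 0 || density <= 0) stop("speeds and densities must be positive")
  list(shape = "circle", centre = as.numeric(centre), diameter = diameter,
       speed = speed, density = density)
}

#' Rasterise a phantom onto velocity and density grids
#'
#' Pixel centre-in-shape rule: grid cell `(i, j)` (centre at
#' `origin + (i-1, j-1) * dx`) takes an inclusion's values when its centre
#' lies inside the circle.
#'
#' @param spec A [phantom_spec()].
#' @return List with `velocity` (a [velocity_model()]) and `density`
#'   (a [density_model()]).
#' @examples
#' sp <- phantom_spec(c(200, 200), 0.5e-3,
#'   inclusions = list(circle_inclusion(c(50e-3, 50e-3))))
#' ph <- make_phantom(sp)
#' @export
make_phantom <- function(spec) {
  nz <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  z <- spec$origin[1] + (seq_len(nz) - 1) * spec$dx
  x <- spec$origin[2] + (seq_len(nx) - 1) * spec$dx
  cgrid <- matrix(spec$background_speed, nz, nx)
  rgrid <- matrix(spec$background_density, nz, nx)
  extent <- c(spec$origin[1] + (nz - 1) * spec$dx,
              spec$origin[2] + (nx - 1) * spec$dx)
  for (inc in spec$inclusions) {
    r <- inc$diameter / 2
    if (inc$centre[1] - r < spec$origin[1] || inc$centre[1] + r > extent[1] ||
        inc$centre[2] - r < spec$origin[2] || inc$centre[2] + r > extent[2])
      stop("inclusion extends outside the grid")
    inside <- outer((z - inc$centre[1])^2, (x - inc$centre[2])^2, `+`) <= r^2
    cgrid[inside] <- inc$speed
    rgrid[inside] <- inc$density
  }
  list(velocity = velocity_model(cgrid, spec$dx, spec$origin),
       density = density_model(rgrid, spec$dx, spec$origin))
}

#' Generate observed shot gathers for a phantom
#'
#' Simulates the observed data for every source of the geometry. With
#' `matched = TRUE` the constant-density solver is used (physics identical
#' to the inversion's); with `matched = FALSE` the variable-density solver
#' propagates through the phantom's density grid, creating a deliberate
#' physics mismatch. To avoid committing the inverse crime, data are by
#' default simulated at a refined time step (`fine_factor` times finer) and
#' decimated back to the inversion's sampling.
#'
#' @param phantom A [phantom_spec()], or the output of [make_phantom()] (a
#'   list with `velocity` and `density`).
#' @param geometry An [acquisition_geometry()].
#' @param wavelet The source [wavelet()] at the inversion time step.
#' @param matched If `TRUE`, constant-density physics.
#' @param nt Number of time samples at the inversion time step.
#' @param fine_factor Integer time-step refinement for data generation
#'   (default 1 = off; temporal refinement changes the solver's numerical
#'   dispersion, so it makes the avoided crime costly — prefer `grid_shift`).
#' @param grid_shift Generation-grid offset in cells (default 0.5): when
#'   `phantom` is a spec, the observed data are simulated on a grid shifted
#'   by this fraction of a cell, so the inversion never sees its own
#'   discretisation of the target (inverse-crime avoidance with identical
#'   dispersion characteristics). Requires a `phantom_spec`; ignored for a
#'   pre-rasterised phantom.
#' @param sponge,scheme As in [simulate_shot()]; `"bilinear"` (default here)
#'   represents the physical transducer positions exactly on both grids.
#' @param sources Which sources to simulate (default all).
#' @return List of [shot_gather()]s indexed by source.
#' @export
generate_observed <- function(phantom, geometry, wavelet, matched = TRUE,
                              nt = NULL, fine_factor = 1L, grid_shift = 0.5,
                              sponge = sponge_spec(), scheme = "bilinear",
                              sources = NULL) {
  if (inherits(phantom, "phantom_spec")) {
    spec <- phantom
    if (grid_shift != 0) {
      shift <- grid_shift * spec$dx
      spec$origin <- spec$origin - shift
      spec$grid_shape <- spec$grid_shape + as.integer(ceiling(grid_shift))
    }
    phantom <- make_phantom(spec)
  }
  model <- phantom$velocity
  if (is.null(nt)) nt <- default_nt(model, geometry, wavelet)
  ff <- max(1L, as.integer(fine_factor))
  dt_f <- wavelet$dt / ff
  wv_f <- if (!is.na(wavelet$centre_frequency) && ff > 1L)
    ricker_wavelet(wavelet$centre_frequency, dt_f)
  else wavelet(resample_linear(wavelet$samples, ff), dt_f,
               wavelet$centre_frequency)
  nt_f <- (nt - 1L) * ff + 1L
  if (is.null(sources)) sources <- seq_len(nrow(geometry$sources))
  out <- vector("list", nrow(geometry$sources))
  for (s in sources) {
    g <- if (matched)
      simulate_shot(model, geometry, wv_f, s, nt = nt_f, sponge = sponge,
                    scheme = scheme)
    else
      simulate_shot_variable_density(model, phantom$density, geometry, wv_f,
                                     s, nt = nt_f, sponge = sponge,
                                     scheme = scheme)
    tr <- g$traces[seq(1, nt_f, by = ff), , drop = FALSE]
    out[[s]] <- shot_gather(tr, wavelet$dt, s,
                            meta = list(matched = matched,
                                        fine_factor = ff, nt = nt))
  }
  out
}

resample_linear <- function(x, ff) {
  if (ff == 1L) return(x)
  n <- length(x)
  stats::approx(seq_len(n), x, xout = seq(1, n, by = 1 / ff))$y
}

#' Region masks for a circular-inclusion phantom
#'
#' Logical masks used when summarising reconstructions: the inclusion
#' interior (eroded by `erode` cells from its boundary), the background
#' annulus between the inclusion boundary and the transducer circle (eroded
#' from both), and the boundary annulus of half-width `erode` cells.
#'
#' @param spec A [phantom_spec()] whose first inclusion is the circle.
#' @param array_diameter Diameter (m) of the transducer circle bounding the
#'   background region.
#' @param erode Erosion margin in cells (default 3).
#' @return List of logical matrices `interior`, `background`, `boundary`.
#' @export
phantom_regions <- function(spec, array_diameter, erode = 3) {
  inc <- spec$inclusions[[1]]
  nz <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  z <- spec$origin[1] + (seq_len(nz) - 1) * spec$dx
  x <- spec$origin[2] + (seq_len(nx) - 1) * spec$dx
  dist <- sqrt(outer((z - inc$centre[1])^2, (x - inc$centre[2])^2, `+`))
  r <- inc$diameter / 2
  m <- erode * spec$dx
  list(interior = dist <= r - m,
       background = dist >= r + m & dist <= array_diameter / 2 - m,
       boundary = abs(dist - r) <= m)
}
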