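#' Acquisition geometry
#'
#' Physical source and receiver positions. Positions are `(z, x)` pairs in
#' metres and must fall inside the physical extent of the model grid they
#' are used with (the absorbing sponge is added outside the user grid, so
#' any position on the grid is in the imaging region).
#'
#' @param sources Matrix (n x 2) of source `(z, x)` positions (m).
#' @param receivers Matrix (n x 2) of receiver `(z, x)` positions (m).
#' @param meta Optional named list (e.g. a shot schedule).
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(sources, receivers, meta = list()) {
  sources <- matrix(as.numeric(sources), ncol = 2)
  receivers <- matrix(as.numeric(receivers), ncol = 2)
  if (!all(is.finite(sources)) || !all(is.finite(receivers)))
    stop("positions must be finite")
  structure(list(sources = sources, receivers = receivers, meta = meta),
            class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry> %d sources, %d receivers\n",
              nrow(x$sources), nrow(x$receivers)))
  invisible(x)
}

#' Circular transducer array
#'
#' `n` co-located single-element sources/receivers equally spaced on a
#' circle, the standard ring-array layout for ultrasound computed
#' tomography. Position `k` sits at angle `2*pi*(k-1)/n` measured from the
#' +x axis towards +z.
#'
#' @param n Number of elements (>= 1).
#' @param diameter Circle diameter (m).
#' @param centre `(z, x)` centre of the circle (m).
#' @return An [acquisition_geometry()] with identical source and receiver
#'   position sets.
#' @examples
#' g <- circular_array(4, diameter = 80e-3, centre = c(50e-3, 50e-3))
#' @export
circular_array <- function(n, diameter, centre = c(0, 0)) {
  if (n < 1) stop("n must be >= 1")
  r <- diameter / 2
  th <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(centre[1] + r * sin(th), centre[2] + r * cos(th))
  acquisition_geometry(pos, pos,
                       meta = list(kind = "circular_array", n = n,
                                   diameter = diameter, centre = centre))
}

#' Rotating two-transducer geometry schedule
#'
#' Emulates a mechanically rotated pair of array transducers: the source
#' transducer occupies one of `n_positions` stations equally spaced on a
#' circle, and the receive transducer visits every station except the
#' source's own and `exclusion` neighbours on each side (which would
#' collide with the source hardware). Each station hosts
#' `elements_per_transducer` elements, and each element of the source
#' transducer fires in turn.
#'
#' @param n_positions Number of transducer stations on the circle.
#' @param elements_per_transducer Elements per transducer.
#' @param exclusion Number of neighbouring stations blocked each side of the
#'   source station.
#' @param diameter Circle diameter (m).
#' @param centre Circle centre `(z, x)` (m).
#' @return A list with `stations` (positions of station centres), `schedule`
#'   (data.frame with one row per source station/receive station pairing),
#'   `n_sources` (total source firings), and `receivers_per_source`.
#' @export
rotating_transducer_geometry <- function(n_positions, elements_per_transducer = 24,
                                         exclusion = 2, diameter = 150e-3,
                                         centre = c(0, 0)) {
  if (n_positions <= 2 * exclusion + 1)
    stop("n_positions must exceed 2 * exclusion + 1")
  th <- 2 * pi * (seq_len(n_positions) - 1) / n_positions
  stations <- cbind(centre[1] + diameter / 2 * sin(th),
                    centre[2] + diameter / 2 * cos(th))
  rows <- list()
  for (s in seq_len(n_positions)) {
    gap <- pmin(abs(seq_len(n_positions) - s),
                n_positions - abs(seq_len(n_positions) - s))
    allowed <- which(gap > exclusion)
    rows[[s]] <- data.frame(source_station = s, receive_station = allowed)
  }
  schedule <- do.call(rbind, rows)
  list(stations = stations, schedule = schedule,
       n_sources = n_positions * elements_per_transducer,
       receivers_per_source = n_positions - 1 - 2 * exclusion,
       elements_per_transducer = elements_per_transducer)
}

#' Corruption specification for acquisition geometry
#'
#' Describes an intermittent source-positioning error: a fraction of the
#' sources is displaced along the array tangent when the observed data are
#' generated, while the inversion keeps assuming the nominal geometry.
#'
#' @param fraction Fraction of sources affected, in `[0, 1]`.
#' @param offset Displacement magnitude (m) along the local tangent.
#' @param contiguous If `TRUE` (default) the affected sources form one
#'   contiguous arc of the array, localising the induced artefact; otherwise
#'   they are drawn independently.
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(fraction = 0.125, offset = 2e-3, contiguous = TRUE) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  structure(list(fraction = fraction, offset = offset, contiguous = contiguous),
            class = "corruption_spec")
}

#' Displace source positions per a corruption specification
#'
#' Applies the positioning error of a [corruption_spec()] to a geometry.
#' Displacement is along the tangent of the circle through the source
#' positions (perpendicular to the radius from the array centre). Only the
#' returned geometry is corrupted; callers use it for observed-data
#' generation and keep the clean geometry for the inversion.
#'
#' @param geometry An [acquisition_geometry()].
#' @param spec A [corruption_spec()].
#' @param seed Integer seed for selecting which sources are affected.
#' @return The corrupted geometry; affected indices in `meta$corrupted`.
#' @export
corrupt_geometry <- function(geometry, spec, seed = 1L) {
  n <- nrow(geometry$sources)
  k <- round(spec$fraction * n)
  if (k == 0) {
    geometry$meta$corrupted <- integer(0)
    return(geometry)
  }
  idx <- withr_seed(seed, {
    if (spec$contiguous && k < n) {
      start <- sample.int(n, 1)
      sort(as.integer(((start - 1 + seq_len(k) - 1) %% n) + 1))
    } else if (k >= n) seq_len(n) else sort(sample.int(n, k))
  })
  ctr <- geometry$meta$centre
  if (is.null(ctr)) ctr <- colMeans(geometry$sources)
  for (i in idx) {
    p <- geometry$sources[i, ]
    rad <- p - ctr
    nr <- sqrt(sum(rad^2))
    tang <- if (nr > 0) c(-rad[2], rad[1]) / nr else c(0, 1)
    geometry$sources[i, ] <- p + spec$offset * tang
  }
  geometry$meta$corrupted <- idx
  geometry
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Map physical positions to injection/extraction stencils on the padded
# grid. Returns 0-based linear cell indices plus weights; `grp` is the
# 0-based position index each entry belongs to.
map_positions <- function(pos, model, W, scheme = c("nearest", "bilinear")) {
  scheme <- match.arg(scheme)
  iz <- (pos[, 1] - model$origin[1]) / model$dx
  ix <- (pos[, 2] - model$origin[2]) / model$dx
  eps <- 1e-9
  if (any(iz < -eps | iz > model$nz - 1 + eps | ix < -eps | ix > model$nx - 1 + eps))
    stop("positions fall outside the physical grid extent")
  nzp <- model$nz + 2L * W
  n <- nrow(pos)
  if (scheme == "nearest") {
    r <- pmin(pmax(round(iz), 0), model$nz - 1)
    cc <- pmin(pmax(round(ix), 0), model$nx - 1)
    list(cell = as.integer((cc + W) * nzp + (r + W)),
         grp = seq_len(n) - 1L, w = rep(1, n))
  } else {
    cells <- integer(0); grps <- integer(0); ws <- numeric(0)
    for (p in seq_len(n)) {
      r0 <- floor(iz[p]); c0 <- floor(ix[p])
      fz <- iz[p] - r0; fx <- ix[p] - c0
      for (dr in 0:1) for (dc in 0:1) {
        wgt <- (if (dr == 0) 1 - fz else fz) * (if (dc == 0) 1 - fx else fx)
        if (wgt <= 0) next
        rr <- min(max(r0 + dr, 0), model$nz - 1)
        cc2 <- min(max(c0 + dc, 0), model$nx - 1)
        cells <- c(cells, as.integer((cc2 + W) * nzp + (rr + W)))
        grps <- c(grps, p - 1L)
        ws <- c(ws, wgt)
      }
    }
    list(cell = cells, grp = grps, w = ws)
  }
}
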