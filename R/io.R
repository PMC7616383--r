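#' Write a shot gather to disk
#'
#' Plain-text dialect: traces as a TSV matrix (`<path>.tsv`, one row per
#' time sample) plus a JSON sidecar (`<path>.json`) carrying `dt`,
#' `source_index` and metadata. Values are serialised at full double
#' precision so the round trip is bit-exact.
#'
#' @param gather A [shot_gather()].
#' @param path Base path (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_gather <- function(gather, path) {
  stopifnot(inherits(gather, "shot_gather"))
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(format(gather$traces, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     tsv, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(dt = gather$dt, source_index = gather$source_index,
                            nt = nrow(gather$traces),
                            n_receivers = ncol(gather$traces),
                            meta = gather$meta),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a shot gather written by [write_gather()]
#'
#' @param path Base path (without extension).
#' @return A [shot_gather()].
#' @export
read_gather <- function(path) {
  tr <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t",
                                    colClasses = "numeric"))
  dimnames(tr) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shot_gather(tr, dt = meta$dt, source_index = meta$source_index,
              meta = as.list(meta$meta))
}

#' Write a velocity or density model to disk
#'
#' Same TSV + JSON-sidecar dialect as [write_gather()].
#' @param model A [velocity_model()] or [density_model()].
#' @param path Base path (without extension).
#' @return Invisibly, the file paths.
#' @export
write_model <- function(model, path) {
  grid <- if (inherits(model, "velocity_model")) model$c else model$rho
  kind <- if (inherits(model, "velocity_model")) "velocity" else "density"
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(format(grid, digits = 17, scientific = TRUE, trim = TRUE),
                     tsv, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(kind = kind, dx = model$dx, origin = model$origin,
                            nz = model$nz, nx = model$nx),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a model written by [write_model()]
#' @param path Base path (without extension).
#' @return A [velocity_model()] or [density_model()].
#' @export
read_model <- function(path) {
  grid <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t",
                                      colClasses = "numeric"))
  dimnames(grid) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$kind, "density"))
    density_model(grid, meta$dx, meta$origin)
  else velocity_model(grid, meta$dx, meta$origin)
}

#' Serialise an inversion report to JSON
#'
#' Writes the per-iteration traces and scalar settings; the final mean and
#' variance grids are included as nested arrays unless `grids = FALSE`.
#'
#' @param report An `inversion_report`.
#' @param path Output file.
#' @param grids Include the final `mu` and `sigma2` grids (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, grids = TRUE) {
  x <- list(iterations = report$iterations, misfit = report$misfit,
            mean_variance = report$mean_variance, alpha = report$alpha,
            seed = report$seed, n_clipped = report$n_clipped)
  if (grids) {
    x$mu <- report$mu
    x$sigma2 <- report$sigma2
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a 2D field as a grayscale PNG
#'
#' Utility for quick-look figures of velocity models, variance images,
#' gradients or masks: values are linearly mapped to [0, 1] over `range`
#' (default the data range) and written as an 8-bit grayscale PNG.
#'
#' @param field Numeric or logical matrix.
#' @param path Output file path.
#' @param range Length-2 value range mapped to black..white.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(field, path, range = NULL) {
  m <- as.matrix(field) * 1.0
  if (is.null(range)) range <- range(m)
  span <- diff(range)
  g <- if (span > 0) (m - range[1]) / span else m * 0
  png::writePNG(pmin(pmax(g, 0), 1), path)
  invisible(path)
}
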