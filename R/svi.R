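#' Mean-field Gaussian prior specification
#'
#' Per-pixel independent Gaussian over sound speed, used only to initialise
#' the variational parameters (the objective carries no regularisation
#' term).
#'
#' @param mu_prior Scalar or grid of prior mean sound speed (m/s).
#' @param var_prior Scalar or grid of prior variance ((m/s)^2), >= 0.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec(1480, 4)  # mean 1480 m/s, std 2 m/s
#' @export
prior_spec <- function(mu_prior = 1480, var_prior = 4) {
  if (any(var_prior < 0)) stop("var_prior must be non-negative")
  structure(list(mu_prior = mu_prior, var_prior = var_prior),
            class = "prior_spec")
}

#' Initialise variational parameters from the prior
#'
#' Broadcasts the prior mean and standard deviation (`sqrt(var_prior)`) onto
#' the model grid. The standard deviation is stored signed; it may change
#' sign during the iteration and is squared only when the variance image is
#' read out.
#'
#' @param prior A [prior_spec()].
#' @param grid_shape Integer `(nz, nx)`.
#' @return An object of class `variational_params` with matrices `mu` and
#'   `sigma`.
#' @export
init_from_prior <- function(prior, grid_shape) {
  nz <- grid_shape[1]; nx <- grid_shape[2]
  bc <- function(v) {
    if (length(v) == 1) matrix(v, nz, nx)
    else {
      v <- as.matrix(v)
      if (!all(dim(v) == c(nz, nx))) stop("prior grid shape mismatch")
      v
    }
  }
  variational_params(bc(prior$mu_prior), sqrt(bc(prior$var_prior)))
}

#' Variational parameters of the mean-field Gaussian posterior
#'
#' @param mu Grid of mean sound speed (m/s).
#' @param sigma Grid of signed standard deviation (m/s), same shape.
#' @return An object of class `variational_params`.
#' @export
variational_params <- function(mu, sigma) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  if (!all(dim(mu) == dim(sigma))) stop("mu and sigma shapes differ")
  if (!all(is.finite(mu)) || !all(is.finite(sigma)))
    stop("variational parameters must be finite")
  structure(list(mu = unname(mu), sigma = unname(sigma)),
            class = "variational_params")
}

#' @export
print.variational_params <- function(x, ...) {
  cat(sprintf("<variational_params> %d x %d grid, mu in [%g, %g] m/s, mean variance %g (m/s)^2\n",
              nrow(x$mu), ncol(x$mu), min(x$mu), max(x$mu), mean(x$sigma^2)))
  invisible(x)
}

#' Draw a model by the reparameterisation trick
#'
#' Samples `epsilon ~ N(0, I)` per pixel and forms
#' `m = mu + sigma * epsilon` elementwise, then clips to the physical band
#' before propagation (solver protection; the unclipped sample identity
#' `model_sample - mu = sigma * epsilon` is preserved in the returned
#' `epsilon`). Uses R's current RNG stream; seed control lives with the
#' caller.
#'
#' @param params A [variational_params()].
#' @param clip Length-2 physical band (m/s) to clip samples to, or `NULL`.
#' @param epsilon Optional fixed standard-normal draw (e.g. a zero matrix to
#'   force the deterministic limit).
#' @return A list of class `sample_draw`: `epsilon`, `model_sample`,
#'   `n_clipped`.
#' @export
sample_model <- function(params, clip = c(1300, 1800), epsilon = NULL) {
  d <- dim(params$mu)
  if (is.null(epsilon)) {
    epsilon <- matrix(stats::rnorm(prod(d)), d[1], d[2])
  } else {
    epsilon <- as.matrix(epsilon)
    if (!all(dim(epsilon) == d)) stop("epsilon shape mismatch")
  }
  m <- params$mu + params$sigma * epsilon
  n_clipped <- 0L
  if (!is.null(clip)) {
    lo <- m < clip[1]; hi <- m > clip[2]
    n_clipped <- sum(lo) + sum(hi)
    m[lo] <- clip[1]; m[hi] <- clip[2]
  }
  structure(list(epsilon = epsilon, model_sample = m,
                 n_clipped = as.integer(n_clipped)),
            class = "sample_draw")
}

#' Mean update
#'
#' Descent step on the data misfit: `mu <- mu - step * delta_m`. The signed
#' standard deviation is untouched. With `sigma = 0` this is exactly the
#' deterministic FWI model update.
#'
#' @param params A [variational_params()].
#' @param gradient A `gradient_image` (misfit gradient `delta_m`).
#' @param step Scalar step size.
#' @return Updated `variational_params`.
#' @export
update_mean <- function(params, gradient, step) {
  if (!all(dim(params$mu) == dim(gradient))) stop("gradient shape mismatch")
  params$mu <- params$mu - step * unclass(gradient)
  params
}

#' Standard-deviation update
#'
#' Recycles the same adjoint-state gradient that updated the mean:
#' `sigma <- sigma - step * (epsilon * delta_m)` elementwise, where
#' `epsilon` is the very draw that produced the sampled model the gradient
#' was computed at. This is a pure elementwise product — no wave simulation
#' occurs here, which is what makes the uncertainty estimate effectively
#' free.
#'
#' @param params A [variational_params()].
#' @param gradient The `gradient_image` computed at this draw's sample.
#' @param draw The [sample_model()] draw used for that gradient.
#' @param step Scalar step size (same as the mean update).
#' @return Updated `variational_params`.
#' @export
update_sigma <- function(params, gradient, draw, step) {
  if (!all(dim(params$sigma) == dim(gradient))) stop("gradient shape mismatch")
  if (!all(dim(draw$epsilon) == dim(gradient)))
    stop("draw/gradient shape mismatch")
  params$sigma <- params$sigma - step * (draw$epsilon * unclass(gradient))
  params
}

#' Variance image
#'
#' The per-pixel uncertainty estimate: the elementwise square of the signed
#' standard deviation.
#'
#' @param params A [variational_params()].
#' @return Matrix of per-pixel variance ((m/s)^2), non-negative.
#' @export
variance_image <- function(params) params$sigma^2

#' Inversion configuration
#'
#' Collects the tunables of [run_inversion()].
#'
#' @param iterations Iteration budget (default 76).
#' @param batch_size Sources per iteration; default `ceiling(n_sources / 51)`
#'   resolved at run time (deterministic round-robin over sources).
#' @param cutoff Low-pass cut-off (Hz) applied identically to observed and
#'   predicted data, or `NULL`.
#' @param step_frac The first mean update's max-norm as a fraction of the
#'   mean prior speed (default 0.005); fixes the step size `alpha`, which is
#'   then held constant and shared by the mean and sigma updates.
#' @param alpha Explicit step size override (skips the `step_frac` rule).
#' @param clip Physical band (m/s) samples are clipped to before
#'   propagation.
#' @param n_draws Monte-Carlo samples per iteration (default 1; gradients
#'   and sigma increments are averaged when larger).
#' @param deterministic If `TRUE`, never sample: run standard deterministic
#'   FWI (the `epsilon = 0` limit); sigma stays at its initial value.
#' @param precondition If `TRUE` (default), divide the batch gradient by the
#'   normalised source-illumination map (plus `precondition_eps`) before the
#'   updates — the standard diagonal pseudo-Hessian compensation for
#'   geometric spreading, without which a fixed-step descent starves the
#'   poorly illuminated interior. The mean and sigma updates always recycle
#'   the identical (preconditioned) gradient.
#' @param precondition_eps Stabilisation constant added to the normalised
#'   illumination (default 0.01).
#' @param sponge,scheme Solver options, as in [simulate_shot()].
#' @param store_trajectory If `TRUE`, keep the per-iteration `mu` grids.
#' @param early_stop_tol If non-`NULL`, stop once the least-squares slope of
#'   the mean-variance trace over the trailing third falls below this
#'   magnitude ((m/s)^2 per iteration).
#' @param checkpoint Optional file path: the full loop state (parameters,
#'   logs, RNG stream) is saved there after every iteration, and a run
#'   started with an existing checkpoint resumes from it, continuing
#'   exactly as the uninterrupted run would have.
#' @return A list of class `inversion_config`.
#' @export
inversion_config <- function(iterations = 76L, batch_size = NULL,
                             cutoff = 700e3, step_frac = 0.005, alpha = NULL,
                             clip = c(1300, 1800), n_draws = 1L,
                             deterministic = FALSE, precondition = TRUE,
                             precondition_eps = 0.01, sponge = sponge_spec(),
                             scheme = "nearest", store_trajectory = FALSE,
                             early_stop_tol = NULL, checkpoint = NULL) {
  structure(list(iterations = as.integer(iterations), batch_size = batch_size,
                 cutoff = cutoff, step_frac = step_frac, alpha = alpha,
                 clip = clip, n_draws = as.integer(n_draws),
                 deterministic = isTRUE(deterministic),
                 precondition = isTRUE(precondition),
                 precondition_eps = precondition_eps, sponge = sponge,
                 scheme = scheme, store_trajectory = isTRUE(store_trajectory),
                 early_stop_tol = early_stop_tol, checkpoint = checkpoint),
            class = "inversion_config")
}

#' Run the stochastic variational FWI loop
#'
#' Per iteration: select the next source batch (deterministic round-robin),
#' draw one per-pixel standard-normal `epsilon`, form the sampled model
#' `m = clip(mu + sigma * epsilon)`, accumulate adjoint-state shot gradients
#' over the batch at the configured low-pass cut-off, then apply the mean
#' update and the standard-deviation update with the same gradient and the
#' same draw. Logs the misfit and the mean of the variance image per
#' iteration.
#'
#' @param observed List of [shot_gather()]s (one per source, indexed by
#'   `source_index`).
#' @param init Initial [variational_params()], e.g. from
#'   [init_from_prior()].
#' @param geometry An [acquisition_geometry()].
#' @param wavelet The source [wavelet()].
#' @param config An [inversion_config()].
#' @param dx,origin Grid geometry of the model (spacing in m).
#' @param seed Integer seed for the sampling stream; recorded in the report.
#' @return An `inversion_report`: per-iteration `misfit`, `mean_variance`,
#'   `batch`, `n_clipped`; `alpha`, `seed`, final `mu` and `sigma`, and the
#'   variance image `sigma2`.
#' @export
run_inversion <- function(observed, init, geometry, wavelet, config,
                          dx, origin = c(0, 0), seed = 1L) {
  stopifnot(inherits(init, "variational_params"),
            inherits(config, "inversion_config"))
  n_src <- length(observed)
  batch <- config$batch_size
  if (is.null(batch)) batch <- max(1L, as.integer(ceiling(n_src / 51)))
  params <- init
  if (!is.null(seed)) set.seed(seed)
  iters <- config$iterations
  misfit <- numeric(0); mvar <- numeric(0); nclip <- integer(0)
  batches <- list(); traj <- if (config$store_trajectory) list() else NULL
  alpha <- config$alpha
  mu0_scale <- mean(abs(params$mu))
  src_cycle <- 0L
  it0 <- 1L
  if (!is.null(config$checkpoint) && file.exists(config$checkpoint)) {
    ck <- readRDS(config$checkpoint)
    params <- ck$params; misfit <- ck$misfit; mvar <- ck$mvar
    nclip <- ck$nclip; batches <- ck$batches; traj <- ck$traj
    alpha <- ck$alpha; src_cycle <- ck$src_cycle
    it0 <- ck$it + 1L
    if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, envir = globalenv())
  }
  zero_eps <- matrix(0, nrow(params$mu), ncol(params$mu))
  if (it0 > iters) {
    warning("checkpoint already covers the requested iterations")
  }
  for (it in seq(it0, length.out = max(0L, iters - it0 + 1L))) {
    b <- ((src_cycle + seq_len(batch) - 1L) %% n_src) + 1L
    src_cycle <- (src_cycle + batch) %% n_src
    grad_sum <- NULL; sig_inc <- NULL; gam <- 0; draw1 <- NULL; ncl <- 0L
    for (k in seq_len(config$n_draws)) {
      draw <- if (config$deterministic)
        sample_model(params, clip = config$clip, epsilon = zero_eps)
      else sample_model(params, clip = config$clip)
      if (k == 1L) draw1 <- draw
      ncl <- ncl + draw$n_clipped
      model_k <- velocity_model(draw$model_sample, dx, origin)
      gk <- NULL; il <- NULL
      for (s in b) {
        sg <- shot_gradient(model_k, geometry, wavelet, observed[[s]],
                            cutoff = config$cutoff, sponge = config$sponge,
                            scheme = config$scheme)
        gi <- attr(sg$gradient, "illum")
        gk <- if (is.null(gk)) unclass(sg$gradient)
              else gk + unclass(sg$gradient)
        il <- if (is.null(il)) gi else il + gi
        gam <- gam + sg$misfit
      }
      if (config$precondition)
        gk <- gk / (il / max(il, 1e-300) + config$precondition_eps)
      grad_sum <- if (is.null(grad_sum)) gk else grad_sum + gk
      # per-draw sigma increment (a single elementwise product; no simulation)
      ek <- draw$epsilon * gk
      sig_inc <- if (is.null(sig_inc)) ek else sig_inc + ek
    }
    grad <- grad_sum / config$n_draws
    gam <- gam / config$n_draws
    if (is.null(alpha)) {
      gmax <- max(abs(grad))
      alpha <- if (gmax > 0) config$step_frac * mu0_scale / gmax else 0
    }
    params <- update_mean(params, grad, alpha)
    if (!config$deterministic) {
      if (config$n_draws == 1L) {
        params <- update_sigma(params, grad, draw1, alpha)
      } else {
        params$sigma <- params$sigma - alpha * (sig_inc / config$n_draws)
      }
    }
    misfit <- c(misfit, gam)
    mvar <- c(mvar, mean(params$sigma^2))
    nclip <- c(nclip, ncl)
    batches[[it]] <- b
    if (config$store_trajectory) traj[[it]] <- params$mu
    if (!is.null(config$checkpoint)) {
      rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
      saveRDS(list(params = params, misfit = misfit, mvar = mvar,
                   nclip = nclip, batches = batches, traj = traj,
                   alpha = alpha, src_cycle = src_cycle, it = it,
                   rng = rng),
              config$checkpoint)
    }
    if (!is.null(config$early_stop_tol) && it >= 10) {
      sl <- tail_slope(mvar)
      if (abs(sl) < config$early_stop_tol) break
    }
  }
  structure(list(misfit = misfit, mean_variance = mvar, batch = batches,
                 n_clipped = nclip, alpha = alpha, seed = seed,
                 iterations = length(misfit), config = config,
                 mu = params$mu, sigma = params$sigma,
                 sigma2 = params$sigma^2, trajectory = traj),
            class = "inversion_report")
}

#' @export
print.inversion_report <- function(x, ...) {
  cat(sprintf(paste0("<inversion_report> %d iterations, final misfit %.4g, ",
                     "mean variance %.4g (m/s)^2, alpha %.4g\n"),
              x$iterations, x$misfit[x$iterations],
              x$mean_variance[x$iterations], x$alpha))
  invisible(x)
}

tail_slope <- function(trace) {
  n <- length(trace)
  k <- max(2L, ceiling(n / 3))
  idx <- (n - k + 1):n
  unname(stats::coef(stats::lm(trace[idx] ~ idx))[2])
}

#' Deterministic full-waveform inversion (reference implementation)
#'
#' Plain gradient-descent FWI: no sampling, no variational parameters —
#' the classical loop that the SVI mean update reduces to when the
#' standard-normal draw is forced to zero. Kept as an independent,
#' minimal implementation so the reduction can be verified bit-for-bit.
#'
#' @param observed List of [shot_gather()]s.
#' @param model0 Starting [velocity_model()].
#' @param geometry,wavelet,config As in [run_inversion()] (`deterministic`
#'   and draw-related settings are ignored).
#' @return List with per-iteration `misfit`, `alpha`, final `model`, and
#'   `trajectory` (per-iteration sound-speed grids when
#'   `config$store_trajectory`).
#' @export
run_fwi <- function(observed, model0, geometry, wavelet, config) {
  n_src <- length(observed)
  batch <- config$batch_size
  if (is.null(batch)) batch <- max(1L, as.integer(ceiling(n_src / 51)))
  m <- model0$c
  alpha <- config$alpha
  m0_scale <- mean(abs(m))
  misfit <- numeric(0)
  traj <- if (config$store_trajectory) list() else NULL
  src_cycle <- 0L
  for (it in seq_len(config$iterations)) {
    b <- ((src_cycle + seq_len(batch) - 1L) %% n_src) + 1L
    src_cycle <- (src_cycle + batch) %% n_src
    mc <- pmin(pmax(m, config$clip[1]), config$clip[2])
    model <- velocity_model(mc, model0$dx, model0$origin)
    g <- NULL; il <- NULL; gam <- 0
    for (s in b) {
      sg <- shot_gradient(model, geometry, wavelet, observed[[s]],
                          cutoff = config$cutoff, sponge = config$sponge,
                          scheme = config$scheme)
      gi <- attr(sg$gradient, "illum")
      g <- if (is.null(g)) unclass(sg$gradient) else g + unclass(sg$gradient)
      il <- if (is.null(il)) gi else il + gi
      gam <- gam + sg$misfit
    }
    if (config$precondition)
      g <- g / (il / max(il, 1e-300) + config$precondition_eps)
    if (is.null(alpha)) {
      gmax <- max(abs(g))
      alpha <- if (gmax > 0) config$step_frac * m0_scale / gmax else 0
    }
    m <- m - alpha * g
    misfit <- c(misfit, gam)
    if (config$store_trajectory) traj[[it]] <- m
  }
  list(misfit = misfit, alpha = alpha,
       model = velocity_model(m, model0$dx, model0$origin),
       trajectory = traj)
}
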