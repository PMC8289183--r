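#' Noise specification for synthetic data
#'
#' @param kind `"none"`, `"multiplicative-gaussian"` (values scaled by
#'   `1 + level * z`) or `"additive-gaussian"` (values shifted by
#'   `level * z`), with `z` standard normal.
#' @param level Noise level (>= 0; e.g. 0.02 for 2% multiplicative noise).
#' @param seed Integer seed making the noise reproducible.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "multiplicative-gaussian",
                                "additive-gaussian"),
                       level = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (length(level) != 1L || !is.finite(level) || level < 0) {
    stop("noise level must be a single value >= 0", call. = FALSE)
  }
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(x, noise) {
  switch(noise$kind,
         "none" = x,
         "multiplicative-gaussian" =
           x * (1 + noise$level * stats::rnorm(length(x))),
         "additive-gaussian" = x + noise$level * stats::rnorm(length(x)))
}

# Run fn with a private RNG stream derived from the noise seed, leaving the
# caller's RNG state untouched.
with_noise_rng <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a (possibly noisy) kinetic trace
#'
#' Wraps [simulate_reduction()] and applies the requested observation noise
#' to every concentration column. The noiseless path is identical to the
#' simulation; noisy paths are bit-reproducible for a fixed seed.
#'
#' @inheritParams simulate_reduction
#' @param noise A [noise_spec()].
#' @return A `kinetic_trace` with provenance `"simulated"` or
#'   `"synthetic-noisy"` and, when noisy, attribute `noise_level`.
#' @export
generate_trace <- function(initial, params, t_grid, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  tr <- simulate_reduction(initial, params, t_grid)
  if (noise$kind == "none") return(tr)
  cols <- c("c_precursor_M", "c_passivated_M", "c_reduced_M", "c_ta_M",
            "c_cit_reactive_M")
  with_noise_rng(noise$seed, function() {
    for (cl in cols) tr[[cl]] <<- apply_noise(tr[[cl]], noise)
  })
  attr(tr, "provenance") <- "synthetic-noisy"
  attr(tr, "noise_level") <- noise$level
  tr
}

#' Render synthetic reaction frames from a progress function
#'
#' Emulates the colour change of the reaction colloid: each frame is a
#' uniform colour interpolated linearly between a start and an end RGB
#' triple according to the progress value at its timestamp. Optional
#' per-channel noise is applied before integer quantization and clipping to
#' 0-255 (clipping biases colours at the extremes of the palette).
#'
#' @param progress Either a function of time returning progress in \[0, 1\]
#'   or a numeric vector of progress values matching `timestamps`.
#' @param timestamps Frame times (s), strictly increasing.
#' @param size Frame height and width in pixels, `c(H, W)`.
#' @param palette List with `start` and `end` RGB triples (0-255). The
#'   default pair shares the same channel sum, which makes the red fraction
#'   of the rendered frames linear in the progress value; palettes with
#'   unequal sums give a monotone but curved response.
#' @param noise A [noise_spec()]; the level is in channel units (0-255).
#' @return A [frame_series()].
#' @export
#' @examples
#' fs <- generate_frames(function(t) t / 10, timestamps = 0:10,
#'                       size = c(4, 4))
generate_frames <- function(progress, timestamps, size = c(8, 8),
                            palette = list(start = c(128, 128, 128),
                                           end = c(230, 90, 64)),
                            noise = noise_spec()) {
  if (!is.list(palette) || !all(c("start", "end") %in% names(palette)) ||
      length(palette$start) != 3L || length(palette$end) != 3L ||
      any(!is.finite(c(palette$start, palette$end))) ||
      any(c(palette$start, palette$end) < 0) ||
      any(c(palette$start, palette$end) > 255)) {
    stop("palette must supply start and end RGB triples in 0-255",
         call. = FALSE)
  }
  p <- if (is.function(progress)) {
    vapply(timestamps, progress, numeric(1))
  } else {
    if (length(progress) != length(timestamps)) {
      stop("progress vector must match timestamps", call. = FALSE)
    }
    as.numeric(progress)
  }
  if (any(!is.finite(p)) || any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("progress values must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  make_frames <- function() {
    lapply(p, function(pi) {
      col <- (1 - pi) * palette$start + pi * palette$end
      fr <- array(rep(col, each = size[1] * size[2]),
                  dim = c(size[1], size[2], 3L))
      if (noise$kind != "none") fr <- apply_noise(fr, noise)
      pmin(pmax(round(fr), 0), 255)
    })
  }
  frames <- if (noise$kind == "none") make_frames() else
    with_noise_rng(noise$seed, make_frames)
  frame_series(timestamps, frames)
}

#' Specification of a particle-size distribution
#'
#' Emulates a TEM-style unimodal size sample with a stated mean and
#' standard deviation.
#'
#' @param mean Mean diameter (nm, > 0).
#' @param sd Standard deviation (nm, >= 0).
#' @param n Number of particles (>= 1).
#' @param family `"normal"` or `"lognormal"` (moment-matched to the stated
#'   mean/sd).
#' @return A list of class `size_distribution_spec`.
#' @export
size_distribution_spec <- function(mean, sd, n,
                                   family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (mean <= 0 || sd < 0 || n < 1) {
    stop("need mean > 0, sd >= 0, n >= 1", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, n = as.integer(n), family = family),
            class = "size_distribution_spec")
}

#' Draw a synthetic particle-size sample
#'
#' @param spec A [size_distribution_spec()].
#' @param seed Integer seed; draws are bit-reproducible.
#' @return Numeric vector of `spec$n` diameters (nm).
#' @export
#' @examples
#' d <- generate_size_distribution(size_distribution_spec(3, 0.5, 100), 1)
generate_size_distribution <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "size_distribution_spec"))
  with_noise_rng(as.integer(seed), function() {
    if (spec$sd == 0) return(rep(spec$mean, spec$n))
    switch(spec$family,
           normal = stats::rnorm(spec$n, spec$mean, spec$sd),
           lognormal = {
             sdlog2 <- log(1 + (spec$sd / spec$mean)^2)
             stats::rlnorm(spec$n, meanlog = log(spec$mean) - sdlog2 / 2,
                           sdlog = sqrt(sdlog2))
           })
  })
}
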