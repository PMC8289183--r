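#' A timestamped series of RGB frames
#'
#' Models the output of a camera pointed at the reaction flask: frames are
#' H x W x 3 arrays with integer channel values in 0-255, all of identical
#' dimensions, at strictly increasing timestamps.
#'
#' @param timestamps Numeric vector of frame times (s), strictly increasing.
#' @param frames List of H x W x 3 numeric arrays (0-255).
#' @return A list of class `frame_series`.
#' @export
frame_series <- function(timestamps, frames) {
  if (length(timestamps) != length(frames)) {
    stop("timestamps and frames must have the same length", call. = FALSE)
  }
  if (length(timestamps) && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  dims <- lapply(frames, dim)
  for (d in dims) {
    if (length(d) != 3L || d[3] != 3L) {
      stop("each frame must be an H x W x 3 array", call. = FALSE)
    }
  }
  if (length(dims) > 1L && !all(vapply(dims[-1], identical, logical(1),
                                      dims[[1]]))) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 255) {
    stop("channel values must lie in 0-255", call. = FALSE)
  }
  structure(list(timestamps = timestamps, frames = frames),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0, 3)
  cat(sprintf("frame_series: %d frames of %d x %d, t = %g..%g s\n",
              length(x$frames), d[1], d[2],
              if (length(x$timestamps)) min(x$timestamps) else NA,
              if (length(x$timestamps)) max(x$timestamps) else NA))
  invisible(x)
}

#' Red-component fraction of a frame
#'
#' The developing plasmon colour of the colloid is tracked as the red
#' channel's share of the total signal. Two conventions are supported:
#' `"pixel_mean"` (default) averages R/(R+G+B) over pixels, excluding pixels
#' with zero total signal; `"channel_mean"` is sum(R)/sum(R+G+B).
#'
#' @param frame An H x W x 3 array (0-255).
#' @param roi Optional rectangular region of interest
#'   `c(row1, row2, col1, col2)` (inclusive); default the whole frame.
#' @param method `"pixel_mean"` or `"channel_mean"`.
#' @return Red fraction in \[0, 1\].
#' @export
#' @examples
#' red_fraction(array(rep(c(255, 0, 0), each = 4), c(2, 2, 3)))  # 1
red_fraction <- function(frame, roi = NULL,
                         method = c("pixel_mean", "channel_mean")) {
  method <- match.arg(method)
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L) {
    stop("frame must be an H x W x 3 array", call. = FALSE)
  }
  if (!is.null(roi)) {
    frame <- frame[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  }
  r <- frame[, , 1]
  total <- frame[, , 1] + frame[, , 2] + frame[, , 3]
  keep <- total > 0
  if (!any(keep)) {
    stop("no signal: every pixel in the region has R+G+B == 0",
         call. = FALSE)
  }
  if (method == "pixel_mean") {
    mean(r[keep] / total[keep])
  } else {
    sum(r[keep]) / sum(total[keep])
  }
}

#' Reaction progress from a frame series
#'
#' Extracts the per-frame red fraction and rescales it to a normalized
#' progress coordinate: 0 at the first frame, 1 at the plateau (the mean red
#' fraction of the final `plateau_k` frames).
#'
#' @param series A [frame_series()] with at least 3 frames.
#' @param plateau_k Number of trailing frames averaged for the plateau
#'   (default 5, capped at the series length).
#' @param roi,method Passed to [red_fraction()].
#' @return A tibble of class `progress_curve` with columns `t_s`,
#'   `red_fraction`, `normalized_progress`.
#' @export
progress_curve <- function(series, plateau_k = 5, roi = NULL,
                           method = "pixel_mean") {
  stopifnot(inherits(series, "frame_series"))
  n <- length(series$frames)
  if (n < 3L) stop("need at least 3 frames", call. = FALSE)
  rf <- vapply(series$frames, red_fraction, numeric(1), roi = roi,
               method = method)
  k <- min(plateau_k, n)
  plateau <- mean(rf[(n - k + 1L):n])
  f0 <- rf[1]
  if (abs(plateau - f0) < .Machine$double.eps * 16) {
    stop("zero dynamic range: plateau red fraction equals the initial value",
         call. = FALSE)
  }
  tibble::new_tibble(
    list(t_s = series$timestamps, red_fraction = rf,
         normalized_progress = (rf - f0) / (plateau - f0)),
    nrow = n, class = "progress_curve"
  )
}

#' Initial reaction rate from a progress curve
#'
#' Normalized progress 1 corresponds to full conversion of the precursor,
#' so the initial rate is the initial slope of the normalized progress
#' multiplied by the starting precursor concentration. The slope is an
#' ordinary least-squares line over the initial window: all points with
#' normalized progress at most `window` (a fraction of the dynamic range,
#' default 10%).
#'
#' Note that a straight-line fit over a finite window underestimates the
#' true initial slope of a concave progress curve; shrink `window` (with
#' dense early sampling) when an accurate tangent is needed.
#'
#' @param curve A `progress_curve` (or any data frame with `t_s` and
#'   `normalized_progress`).
#' @param c_au_0 Initial precursor concentration (mol/L, > 0).
#' @param window Fraction of the dynamic range defining the fit window
#'   (default 0.1).
#' @return Initial rate (mol/L/s) with attribute `n_points`.
#' @export
estimate_initial_rate <- function(curve, c_au_0, window = 0.1) {
  if (length(c_au_0) != 1L || !is.finite(c_au_0) || c_au_0 <= 0) {
    stop("c_au_0 must be a single positive concentration", call. = FALSE)
  }
  t <- curve$t_s
  p <- curve$normalized_progress
  # leading run of points inside the window (late dips back below the
  # threshold, e.g. from noise, are not part of the initial window)
  first_out <- which(p > window)[1]
  sel <- seq_len(if (is.na(first_out)) length(p) else first_out - 1L)
  if (length(sel) < 3L) {
    stop(sprintf("fewer than 3 points in the initial window (%d)",
                 length(sel)), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, t[sel]), p[sel])
  slope <- fit$coefficients[2]
  structure(unname(slope * c_au_0), n_points = length(sel))
}

#' Reaction order by log-log regression
#'
#' Ordinary least-squares fit of log(initial rate) against log(reductant
#' concentration); the slope is the apparent reaction order, the intercept
#' the log rate coefficient.
#'
#' @param rates Initial rates (mol/L/s, > 0).
#' @param concentrations Matching reductant concentrations (mol/L, > 0).
#' @return A list with `order` (slope), `log_intercept`, and `r_squared`.
#' @export
#' @examples
#' fit_reaction_order(c(1, 4, 9), c(1, 2, 3))  # order 2
fit_reaction_order <- function(rates, concentrations) {
  if (length(rates) != length(concentrations)) {
    stop("rates and concentrations must have equal length", call. = FALSE)
  }
  if (length(rates) < 2L) {
    stop("need at least 2 (rate, concentration) pairs", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(!is.finite(concentrations)) ||
      any(rates <= 0) || any(concentrations <= 0)) {
    stop("rates and concentrations must be strictly positive", call. = FALSE)
  }
  x <- log10(concentrations)
  y <- log10(rates)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  list(order = unname(stats::coef(fit)[2]),
       log_intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}
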