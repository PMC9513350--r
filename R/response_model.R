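# Synthetic cortical response layer.  A threshold-shifted Hill function
# maps charge per phase to normalized peak depolarization, and a
# spatiotemporal generator produces voltage-sensitive-dye (VSD) style
# delta-F/F movies: each stimulus contributes a Gaussian spatial profile
# (widening with post-stimulus time to model propagation) times a temporal
# kernel (alpha-function rise to the positive peak, slow Gaussian
# undershoot), pulses arriving shortly after a predecessor are attenuated
# by a fixed inhibition gain, contributions sum, and i.i.d. Gaussian pixel
# noise is added.

#' Dose-response parameters of the threshold-shifted Hill model
#'
#' The three parameters carry their conventional meanings: no response at
#' or below the threshold charge, half of the maximum at the half-max
#' charge, steepness set by the Hill coefficient.
#'
#' @param i_th_nc Threshold charge, nC/phase (default 0.9).
#' @param i_50_nc Half-maximum charge, nC/phase (default 2.4).
#' @param n Hill coefficient (default 2.5).
#' @return An object of class `"hill_params"`.
#' @export
hill_params <- function(i_th_nc = 0.9, i_50_nc = 2.4, n = 2.5) {
  if (i_th_nc < 0 || i_50_nc <= i_th_nc)
    stop("need 0 <= i_th_nc < i_50_nc")
  if (n <= 0) stop("'n' must be > 0")
  structure(list(i_th_nc = i_th_nc, i_50_nc = i_50_nc, n = n),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> I_th=%.4g nC, I_50=%.4g nC, N=%.4g\n",
              x$i_th_nc, x$i_50_nc, x$n))
  invisible(x)
}

#' Normalized response amplitude for a stimulus charge
#'
#' `0` for `q <= i_th`; above threshold
#' `(q - i_th)^n / ((q - i_th)^n + (i_50 - i_th)^n)`.
#' Continuous at the threshold, strictly increasing above it, bounded in
#' `[0, 1)`, and exactly 0.5 at `q = i_50`.
#'
#' @param q_nc Charge per phase, nC (vectorized, >= 0).
#' @param params A [hill_params()].
#' @return Normalized response amplitude(s) in `[0, 1)`.
#' @examples
#' hill_response(2.4, hill_params())  # 0.5
#' @export
hill_response <- function(q_nc, params = hill_params()) {
  if (any(q_nc < 0)) stop("'q_nc' must be >= 0")
  d <- pmax(q_nc - params$i_th_nc, 0)
  k <- (params$i_50_nc - params$i_th_nc)^params$n
  ifelse(d > 0, d^params$n / (d^params$n + k), 0)
}

#' Fit the threshold-shifted Hill model to dose-response points
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) over
#' a fixed multi-start grid, so the fit is deterministic for given data.
#' Parameterized as (i_th, delta = i_50 - i_th, n) with lower bounds
#' keeping i_th >= 0, delta > 0, n > 0.
#'
#' @param charge_nc Charges per phase, nC; at least 5 points spanning both
#'   sides of the half-maximum.
#' @param response Normalized response amplitudes.
#' @return An object of class `"hill_fit"`: `params` ([hill_params()]),
#'   `residual_norm`, `deviance`, `fitted`, `n_starts`.  Degenerate data
#'   (constant responses) raise an error of class `"icmstim_fit_error"`.
#' @examples
#' q <- seq(1, 8, length.out = 8)
#' fit_hill(q, hill_response(q))$params
#' @export
fit_hill <- function(charge_nc, response) {
  if (length(charge_nc) != length(response))
    stop("'charge_nc' and 'response' lengths differ")
  if (length(charge_nc) < 5)
    stop("need at least 5 dose-response points")
  if (stats::sd(response) == 0 || max(response) <= 0)
    stop(structure(
      class = c("icmstim_fit_error", "error", "condition"),
      list(message = "degenerate dose-response data: responses carry no dose information",
           call = sys.call())))
  rmax <- max(response)
  half <- rmax / 2
  if (!any(response < half) || !any(response > half))
    warning("points do not span both sides of the half-maximum; fit may be poorly constrained")
  q_half <- charge_nc[which.min(abs(response - half))]
  q_low <- suppressWarnings(min(charge_nc[response > 0.05 * rmax]))
  if (!is.finite(q_low)) q_low <- min(charge_nc)
  resid_fn <- function(p) {
    response - hill_response(charge_nc,
                             hill_params(p[1], p[1] + p[2], p[3]))
  }
  lower <- c(0, 1e-6, 1e-3)
  upper <- c(max(charge_nc), 10 * max(charge_nc), 50)
  starts <- expand.grid(i_th = c(0, 0.5, 0.9) * q_low,
                        n = c(1, 2.5, 5))
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    p0 <- c(starts$i_th[j],
            max(q_half - starts$i_th[j], 0.1 * q_half, 1e-3),
            starts$n[j])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop(structure(
      class = c("icmstim_fit_error", "error", "condition"),
      list(message = "Hill fit failed from every start", call = sys.call())))
  p <- best$par
  params <- hill_params(p[1], p[1] + p[2], p[3])
  structure(
    list(params = params, deviance = best$deviance,
         residual_norm = sqrt(best$deviance),
         fitted = hill_response(charge_nc, params),
         n_starts = nrow(starts)),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> I_th=%.4g nC, I_50=%.4g nC, N=%.4g, residual norm %.3g\n",
    x$params$i_th_nc, x$params$i_50_nc, x$params$n, x$residual_norm))
  invisible(x)
}

#' Response kinetics of the synthetic VSD generator
#'
#' Defaults emulate the stereotyped cortical response to a single
#' intracortical pulse: depolarization peaking 11-15 ms post-stimulus
#' (default 13), a shallow hyperpolarizing undershoot around 100 ms, and
#' an initial activation focus a few hundred micrometers wide that spreads
#' over the following milliseconds.  Pulses delivered within the
#' inhibition window of a predecessor are attenuated by the inhibition
#' gain (the window matches the ~20 ms recruitment of inhibitory
#' circuitry).
#'
#' @param t_peak_ms Time of the positive peak, ms.
#' @param undershoot_time_ms Center of the negative undershoot, ms.
#' @param undershoot_depth Undershoot depth as a fraction of the peak.
#' @param undershoot_sigma_ms Gaussian half-width of the undershoot, ms.
#' @param spatial_sigma_mm Gaussian radius of the focus at stimulus time,
#'   mm.
#' @param spatial_growth_mm_per_ms Radius growth rate (propagation), mm/ms.
#' @param inhibition_window_ms Inter-pulse interval below which the later
#'   pulse is attenuated, ms.
#' @param inhibition_gain Attenuation factor in `[0, 1]` applied per
#'   preceding pulse in the chain.
#' @return An object of class `"response_kinetics"`.
#' @export
response_kinetics <- function(t_peak_ms = 13, undershoot_time_ms = 100,
                              undershoot_depth = 0.15,
                              undershoot_sigma_ms = 30,
                              spatial_sigma_mm = 0.1,
                              spatial_growth_mm_per_ms = 0.025,
                              inhibition_window_ms = 20,
                              inhibition_gain = 0.5) {
  if (t_peak_ms <= 0 || t_peak_ms >= undershoot_time_ms)
    stop("need 0 < t_peak_ms < undershoot_time_ms")
  if (undershoot_depth < 0 || undershoot_depth > 1 ||
      inhibition_gain < 0 || inhibition_gain > 1)
    stop("gains/depths must lie in [0, 1]")
  if (spatial_sigma_mm <= 0 || undershoot_sigma_ms <= 0)
    stop("spatial and undershoot widths must be > 0")
  structure(
    list(t_peak_ms = t_peak_ms, undershoot_time_ms = undershoot_time_ms,
         undershoot_depth = undershoot_depth,
         undershoot_sigma_ms = undershoot_sigma_ms,
         spatial_sigma_mm = spatial_sigma_mm,
         spatial_growth_mm_per_ms = spatial_growth_mm_per_ms,
         inhibition_window_ms = inhibition_window_ms,
         inhibition_gain = inhibition_gain),
    class = "response_kinetics")
}

#' Temporal kernel of the synthetic VSD response
#'
#' Alpha-function rise/decay normalized to 1 at `t_peak`, minus a Gaussian
#' undershoot centered at `undershoot_time_ms`:
#' `(t/tp) exp(1 - t/tp) - depth * exp(-(t - tu)^2 / (2 su^2))` for
#' `t >= 0`, zero before the stimulus.
#'
#' @param t_ms Post-stimulus time, ms (vectorized; negative times give 0).
#' @param kinetics A [response_kinetics()].
#' @return Kernel values (unitless, peak ~1).
#' @export
vsd_kernel <- function(t_ms, kinetics = response_kinetics()) {
  tp <- kinetics$t_peak_ms
  pos <- ifelse(t_ms >= 0, (t_ms / tp) * exp(1 - t_ms / tp), 0)
  neg <- kinetics$undershoot_depth *
    exp(-(t_ms - kinetics$undershoot_time_ms)^2 /
          (2 * kinetics$undershoot_sigma_ms^2))
  ifelse(t_ms >= 0, pos - neg, 0)
}

# Inhibition chain: pulse k is attenuated by gain relative to pulse k-1
# when its onset falls inside the predecessor's window; gaps longer than
# the window reset the chain to 1.  Simultaneous pulses form one volley
# and share the predecessor's gain (multi-site stimulation is not
# sequential inhibition).
.inhibition_gains <- function(onsets_ms, kinetics) {
  ord <- order(onsets_ms)
  g <- numeric(length(onsets_ms))
  prev_gain <- 1
  prev_t <- -Inf
  for (i in ord) {
    gap <- onsets_ms[i] - prev_t
    gain <- if (gap == 0) prev_gain
    else if (gap <= kinetics$inhibition_window_ms)
      prev_gain * kinetics$inhibition_gain
    else 1
    g[i] <- gain
    prev_gain <- gain
    prev_t <- onsets_ms[i]
  }
  g
}

#' Generate a synthetic VSD delta-F/F movie
#'
#' Each electrode's stimulus contributes
#' `gain * hill_response(charge) * vsd_kernel(t - onset) *
#'  exp(-d^2 / (2 sigma(t - onset)^2))`
#' with `sigma(t) = spatial_sigma + growth * t`; contributions sum, and
#' i.i.d. Gaussian noise (scaled by `1/sqrt(n_trials)` to model trial
#' averaging) is added.  Deterministic for a given seed; the caller's RNG
#' state is restored on exit.
#'
#' @param electrodes Data frame with columns `x_mm`, `y_mm`, `charge_nc`,
#'   `onset_ms` (one row per stimulus pulse), all positions inside the
#'   imaged field.
#' @param params A [hill_params()].
#' @param kinetics A [response_kinetics()].
#' @param n_frames Number of 1 ms frames.
#' @param noise_sd Per-pixel, per-frame Gaussian noise SD (delta-F/F
#'   units) of a single trial.
#' @param seed Integer seed for the noise; `NULL` uses the current RNG.
#' @param n_trials Number of averaged trials (16 mirrors the imaging
#'   protocol).
#' @param field_mm Imaged field width, mm.
#' @param n_px Pixels per side.
#' @return An object of class `"vsd_movie"`: 3-D array `frames`
#'   (`n_px` rows x `n_px` columns x `n_frames`, one frame per ms),
#'   `pixel_pitch_mm`, `frame_rate_hz`, `electrodes` and the applied
#'   per-pulse `gains`.
#' @export
synth_vsd_movie <- function(electrodes, params = hill_params(),
                            kinetics = response_kinetics(),
                            n_frames = 200, noise_sd = 0, seed = NULL,
                            n_trials = 1, field_mm = 6.25, n_px = 100) {
  electrodes <- as.data.frame(electrodes)
  need <- c("x_mm", "y_mm", "charge_nc", "onset_ms")
  if (!all(need %in% names(electrodes)))
    stop("'electrodes' needs columns x_mm, y_mm, charge_nc, onset_ms")
  pitch <- field_mm / n_px
  if (nrow(electrodes) > 0 &&
      (any(electrodes$x_mm < 0 | electrodes$x_mm > field_mm) ||
       any(electrodes$y_mm < 0 | electrodes$y_mm > field_mm)))
    stop("electrode positions must lie inside the imaged field")
  px <- (seq_len(n_px) - 0.5) * pitch  # pixel-center coordinates
  xg <- matrix(px, n_px, n_px, byrow = TRUE)   # column -> x
  yg <- matrix(px, n_px, n_px, byrow = FALSE)  # row -> y
  gains <- .inhibition_gains(electrodes$onset_ms, kinetics)
  frames <- array(0, dim = c(n_px, n_px, n_frames))
  times <- seq_len(n_frames) - 1
  for (e in seq_len(nrow(electrodes))) {
    amp <- gains[e] * hill_response(electrodes$charge_nc[e], params)
    if (amp == 0) next
    d2 <- (xg - electrodes$x_mm[e])^2 + (yg - electrodes$y_mm[e])^2
    rel <- times - electrodes$onset_ms[e]
    kt <- vsd_kernel(rel, kinetics)
    for (f in which(rel >= 0 & kt != 0)) {
      sig <- kinetics$spatial_sigma_mm +
        kinetics$spatial_growth_mm_per_ms * rel[f]
      frames[, , f] <- frames[, , f] +
        amp * kt[f] * exp(-d2 / (2 * sig^2))
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old_seed)) {
          if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old_seed, envir = globalenv())
      })
      set.seed(seed)
    }
    frames <- frames + array(
      stats::rnorm(length(frames), 0, noise_sd / sqrt(n_trials)),
      dim = dim(frames))
  }
  structure(
    list(frames = frames, pixel_pitch_mm = pitch, frame_rate_hz = 1000,
         electrodes = electrodes, gains = gains, params = params,
         kinetics = kinetics),
    class = "vsd_movie")
}

#' @export
print.vsd_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<vsd_movie> %d x %d px, %d frames @ %g Hz, pitch %.4g mm, %d pulses\n",
    d[1], d[2], d[3], x$frame_rate_hz, x$pixel_pitch_mm,
    nrow(x$electrodes)))
  invisible(x)
}

# Pixels whose centers fall inside a rectangular region of interest given
# in mm; roi = NULL selects the whole field.
.roi_indices <- function(movie, roi) {
  n_px <- dim(movie$frames)[1]
  px <- (seq_len(n_px) - 0.5) * movie$pixel_pitch_mm
  if (is.null(roi)) return(list(rows = seq_len(n_px), cols = seq_len(n_px)))
  rows <- which(px >= roi$y_mm[1] & px <= roi$y_mm[2])
  cols <- which(px >= roi$x_mm[1] & px <= roi$x_mm[2])
  if (length(rows) == 0 || length(cols) == 0)
    stop("empty region of interest")
  list(rows = rows, cols = cols)
}

#' Rectangular region of interest around a point
#'
#' @param x_mm,y_mm Center, mm.
#' @param half_width_mm Half-width of the square ROI, mm.
#' @return ROI list usable with [peak_amplitude()].
#' @export
roi_around <- function(x_mm, y_mm, half_width_mm = 0.2) {
  list(x_mm = c(x_mm - half_width_mm, x_mm + half_width_mm),
       y_mm = c(y_mm - half_width_mm, y_mm + half_width_mm))
}

#' Positive peak of the ROI-averaged delta-F/F trace
#'
#' @param movie A `"vsd_movie"`.
#' @param roi ROI list (`x_mm`, `y_mm` ranges in mm) or `NULL` for the
#'   whole field.
#' @param window_ms Two-element time window, ms; default whole movie.
#' @return List with `peak` (delta-F/F), `t_peak_ms` and the full ROI
#'   `trace`.
#' @export
peak_amplitude <- function(movie, roi = NULL, window_ms = NULL) {
  stopifnot(inherits(movie, "vsd_movie"))
  idx <- .roi_indices(movie, roi)
  trace <- apply(movie$frames[idx$rows, idx$cols, , drop = FALSE], 3, mean)
  times <- seq_along(trace) - 1
  keep <- if (is.null(window_ms)) rep(TRUE, length(trace)) else
    times >= window_ms[1] & times <= window_ms[2]
  if (!any(keep)) stop("empty time window")
  k <- which(keep)[which.max(trace[keep])]
  list(peak = trace[k], t_peak_ms = times[k], trace = trace)
}

#' Spatial line profile of the delta-F/F signal
#'
#' Bilinearly samples the movie along a line, averaged over a time window.
#'
#' @param movie A `"vsd_movie"`.
#' @param from_mm,to_mm Endpoints `c(x, y)` in mm, inside the field.
#' @param window_ms Two-element averaging window, ms.
#' @param n Number of sample points along the line.
#' @return Data frame with `s_mm` (distance along the line), `x_mm`,
#'   `y_mm`, `dff`.
#' @export
line_profile <- function(movie, from_mm, to_mm, window_ms, n = 200) {
  stopifnot(inherits(movie, "vsd_movie"))
  times <- seq_len(dim(movie$frames)[3]) - 1
  keep <- times >= window_ms[1] & times <= window_ms[2]
  if (!any(keep)) stop("empty time window")
  img <- apply(movie$frames[, , keep, drop = FALSE], c(1, 2), mean)
  tseq <- seq(0, 1, length.out = n)
  xs <- from_mm[1] + tseq * (to_mm[1] - from_mm[1])
  ys <- from_mm[2] + tseq * (to_mm[2] - from_mm[2])
  vals <- .bilinear(img, movie$pixel_pitch_mm, xs, ys)
  data.frame(
    s_mm = tseq * sqrt(sum((to_mm - from_mm)^2)),
    x_mm = xs, y_mm = ys, dff = vals)
}

.bilinear <- function(img, pitch, xs, ys) {
  n_px <- nrow(img)
  # pixel-center i sits at (i - 0.5) * pitch
  cx <- pmin(pmax(xs / pitch + 0.5, 1), n_px)
  cy <- pmin(pmax(ys / pitch + 0.5, 1), n_px)
  c0 <- pmin(floor(cx), n_px - 1)
  r0 <- pmin(floor(cy), n_px - 1)
  fx <- cx - c0
  fy <- cy - r0
  img[cbind(r0, c0)] * (1 - fx) * (1 - fy) +
    img[cbind(r0, c0 + 1)] * fx * (1 - fy) +
    img[cbind(r0 + 1, c0)] * (1 - fx) * fy +
    img[cbind(r0 + 1, c0 + 1)] * fx * fy
}

#' Count distinct activation foci in a movie frame
#'
#' Thresholds the frame at a fraction of its maximum and counts
#' 8-connected components of supra-threshold pixels.  Two nearby sources
#' merge into one focus once their profiles overlap above the level.
#'
#' @param movie A `"vsd_movie"`.
#' @param t_ms Frame time, ms.
#' @param level Threshold as a fraction of the frame maximum.
#' @return Number of foci (0 for a non-positive frame).
#' @export
count_activation_foci <- function(movie, t_ms, level = 0.5) {
  frame <- movie$frames[, , t_ms + 1]
  mx <- max(frame)
  if (mx <= 0) return(0L)
  mask <- frame >= level * mx
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  comp <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        nb <- (cc - 1L) * nr + rr
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

#' Synthetic dose-response table from an amplitude series
#'
#' Links the response layer to the current generator: each commanded
#' amplitude is quantized by the 6-bit DAC and converted to charge per
#' phase (quantized amplitude x phase duration), then mapped through the
#' Hill model, with optional Gaussian noise.
#'
#' @param amplitudes_ua Commanded amplitudes, uA (default the ~5 uA-step
#'   series 5..40 used for dose-response runs).
#' @param phase_dur_ms Phase duration, ms.
#' @param params A [hill_params()].
#' @param settings A [generator_settings()].
#' @param noise_sd Gaussian noise SD on the normalized response.
#' @param seed Seed for the noise; `NULL` uses the current RNG.
#' @return Data frame with `amplitude_ua` (quantized), `charge_nc`,
#'   `response_norm`.
#' @export
synth_dose_response <- function(amplitudes_ua = seq(5, 40, by = 5),
                                phase_dur_ms = 0.2,
                                params = hill_params(),
                                settings = generator_settings(),
                                noise_sd = 0, seed = NULL) {
  amp_q <- vapply(amplitudes_ua, function(a)
    quantize_amplitude(a, settings)$amplitude_ua, 0)
  charge <- amp_q * phase_dur_ms  # uA x ms = nC
  resp <- hill_response(charge, params)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
  }
  data.frame(amplitude_ua = amp_q, charge_nc = charge,
             response_norm = resp)
}

#' Write a dose-response table to CSV
#'
#' @param table Data frame with `charge_nc` and `response_norm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(table, path) {
  utils::write.csv(table[, c("charge_nc", "response_norm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a dose-response table from CSV
#'
#' @param path CSV with columns `charge_nc`, `response_norm`.
#' @return Data frame.
#' @export
read_dose_response_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("charge_nc", "response_norm") %in% names(d)))
    stop("dose-response CSV needs columns charge_nc, response_norm")
  d
}

#' Write a VSD movie as a directory of CSV frames
#'
#' One CSV per frame (`frame_000.csv`, ...) plus `meta.json` holding the
#' pixel pitch and frame rate.
#'
#' @param movie A `"vsd_movie"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_vsd_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- dim(movie$frames)[3]
  for (f in seq_len(nt)) {
    utils::write.table(
      movie$frames[, , f],
      file.path(dir, sprintf("frame_%03d.csv", f - 1)),
      sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(pixel_pitch_mm = movie$pixel_pitch_mm,
         frame_rate_hz = movie$frame_rate_hz, n_frames = nt),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a VSD movie written by [write_vsd_movie()]
#'
#' @param dir Movie directory.
#' @return A `"vsd_movie"` (without electrode metadata).
#' @export
read_vsd_movie <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  frames <- lapply(seq_len(meta$n_frames) - 1, function(f)
    as.matrix(utils::read.table(
      file.path(dir, sprintf("frame_%03d.csv", f)), sep = ",")))
  arr <- array(unlist(frames), dim = c(dim(frames[[1]]), meta$n_frames))
  structure(
    list(frames = arr, pixel_pitch_mm = meta$pixel_pitch_mm,
         frame_rate_hz = meta$frame_rate_hz,
         electrodes = data.frame(x_mm = numeric(), y_mm = numeric(),
                                 charge_nc = numeric(),
                                 onset_ms = numeric()),
         gains = numeric(), params = NULL, kinetics = NULL),
    class = "vsd_movie")
}
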