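#' Specification of a synthetic two-channel FRET image stack
#'
#' Parameters for [simulate_fret_stack()], which emulates paired CFP/YFP
#' recordings of a ratiometric Ca2+ indicator (TN-XXL convention: a Ca2+
#' rise increases FRET, so YFP rises while CFP falls). The dendritic
#' transient rises during the stimulus simultaneously at all arbor pixels
#' and decays monoexponentially afterwards; soma pixels, if present, follow
#' the same time course with a slower decay constant.
#'
#' `transient_amplitude` is parameterised on the ratio, not on the
#' channels: it is the ground-truth peak ratio change of the trial, i.e.
#' the average percent ratio change over the representative 400-700 ms
#' window after stimulus cessation.
#'
#' @param shape `c(nx, ny, n_frames)`.
#' @param frame_interval frame spacing (s).
#' @param arbor_skeleton integer matrix of pixel coordinates (columns x, y)
#'   tracing the dendrite; `NULL` draws a branched arbor at random.
#' @param baseline_cfp,baseline_yfp resting single-pixel intensities of the
#'   two channels on the arbor.
#' @param transient_amplitude ground-truth peak ratio change (% dR/R0).
#' @param decay_tau dendritic decay constant (s).
#' @param soma_tau somatic decay constant (s), slower than `decay_tau`.
#' @param soma_center,soma_radius optional soma disc (pixels); `NULL` for
#'   no soma.
#' @param noise_sd Gaussian intensity noise s.d.
#' @param bleach_rate photobleaching rate applied to both channels (1/s).
#' @param background background intensity outside the arbor.
#' @param seed integer seed.
#' @return an object of class `fret_stack_spec`.
#' @export
fret_stack_spec <- function(shape = c(48, 48, 80), frame_interval = 0.05,
                            arbor_skeleton = NULL,
                            baseline_cfp = 800, baseline_yfp = 800,
                            transient_amplitude = 30, decay_tau = 1,
                            soma_tau = 3, soma_center = NULL, soma_radius = 3,
                            noise_sd = 0, bleach_rate = 0, background = 40,
                            seed = 1L) {
  if (transient_amplitude < 0)
    stop("`transient_amplitude` must be non-negative")
  if (decay_tau <= 0 || soma_tau <= 0) stop("decay constants must be positive")
  if (length(shape) != 3L || any(shape < 4))
    stop("`shape` must be c(nx, ny, n_frames) with nx, ny, n_frames >= 4")
  structure(list(shape = as.integer(shape), frame_interval = frame_interval,
                 arbor_skeleton = arbor_skeleton,
                 baseline_cfp = baseline_cfp, baseline_yfp = baseline_yfp,
                 transient_amplitude = transient_amplitude,
                 decay_tau = decay_tau, soma_tau = soma_tau,
                 soma_center = soma_center, soma_radius = soma_radius,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 background = background, seed = as.integer(seed)),
            class = "fret_stack_spec")
}

# random branched arbor skeleton: a main neurite plus side branches
random_arbor_skeleton <- function(nx, ny, n_branches = 4) {
  path <- cbind(x = round(seq(4, nx - 3, length.out = nx)),
                y = round(ny / 2 + cumsum(stats::rnorm(nx, 0, 0.7))))
  pts <- path
  starts <- path[round(seq(0.2, 0.8, length.out = n_branches) * nrow(path)), ,
                 drop = FALSE]
  for (b in seq_len(nrow(starts))) {
    len <- round(ny / 3)
    dir <- if (b %% 2 == 0) 1 else -1
    br <- cbind(x = starts[b, 1] + round(cumsum(stats::rnorm(len, 0, 0.5))),
                y = starts[b, 2] + dir * seq_len(len))
    pts <- rbind(pts, br)
  }
  pts[, 1] <- pmin(pmax(pts[, 1], 2L), nx - 1L)
  pts[, 2] <- pmin(pmax(pts[, 2], 2L), ny - 1L)
  unique(pts)
}

# dilate a set of pixel coordinates by one pixel (8-neighbourhood)
dilate_coords <- function(coords, nx, ny) {
  off <- expand.grid(dx = -1:1, dy = -1:1)
  out <- unique(do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    cbind(coords[, 1] + off$dx[i], coords[, 2] + off$dy[i]))))
  out <- out[out[, 1] >= 1 & out[, 1] <= nx & out[, 2] >= 1 & out[, 2] <= ny, ,
             drop = FALSE]
  out
}

# ground-truth percent ratio-change time course on the frame grid,
# normalised so its mean over [stim_end + w1, stim_end + w2] is `amplitude`
fret_transient_course <- function(frame_times, onset, stim_end, amplitude,
                                  tau, window = c(0.4, 0.7)) {
  g <- numeric(length(frame_times))
  rising <- frame_times >= onset & frame_times < stim_end
  g[rising] <- (frame_times[rising] - onset) / (stim_end - onset)
  after <- frame_times >= stim_end
  g[after] <- exp(-(frame_times[after] - stim_end) / tau)
  in_win <- frame_times >= stim_end + window[1] &
    frame_times <= stim_end + window[2]
  if (!any(in_win))
    stop("frame times do not cover the representative window")
  amplitude * g / mean(g[in_win])
}

#' Simulate a paired CFP/YFP FRET image stack
#'
#' Builds co-registered CFP and YFP stacks containing a dendritic arbor
#' whose FRET ratio rises during the stimulus and decays exponentially
#' after it, with anti-correlated channel intensities (YFP up, CFP down),
#' optional slower soma kinetics, photobleaching, and Gaussian noise. The
#' ground-truth mask and percent ratio-change trace are returned alongside
#' the stacks so downstream stages can be validated against them.
#'
#' @param spec a [fret_stack_spec()].
#' @param protocol a [stimulus_protocol()].
#' @return an object of class `image_stack_pair`: a list with `cfp`, `yfp`
#'   (arrays nx x ny x frames), `frame_times` (s), `protocol`, and ground
#'   truth `truth = list(mask, skeleton, dr, dr_soma)` where `dr` is the
#'   percent ratio-change time course of the dendrite.
#' @export
simulate_fret_stack <- function(spec, protocol) {
  stopifnot(inherits(spec, "fret_stack_spec"),
            inherits(protocol, "stimulus_protocol"))
  set.seed(spec$seed)
  nx <- spec$shape[1]; ny <- spec$shape[2]; nf <- spec$shape[3]
  ft <- (seq_len(nf) - 1L) * spec$frame_interval
  win <- stim_window(protocol)

  skel <- spec$arbor_skeleton
  if (is.null(skel)) skel <- random_arbor_skeleton(nx, ny)
  if (!nrow(skel)) stop("arbor skeleton must be non-empty")
  mask_coords <- dilate_coords(skel, nx, ny)
  mask <- matrix(FALSE, nx, ny)
  mask[mask_coords] <- TRUE

  soma <- matrix(FALSE, nx, ny)
  if (!is.null(spec$soma_center)) {
    gx <- matrix(seq_len(nx), nx, ny)
    gy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    soma <- (gx - spec$soma_center[1])^2 + (gy - spec$soma_center[2])^2 <=
      spec$soma_radius^2
    mask <- mask | soma
  }

  dr <- fret_transient_course(ft, win[1], win[2], spec$transient_amplitude,
                              spec$decay_tau)
  dr_soma <- if (any(soma))
    fret_transient_course(ft, win[1], win[2], spec$transient_amplitude,
                          spec$soma_tau)
  else NULL

  bleach <- exp(-spec$bleach_rate * ft)
  cfp <- array(spec$background, dim = c(nx, ny, nf))
  yfp <- array(spec$background, dim = c(nx, ny, nf))
  dend <- mask & !soma
  for (f in seq_len(nf)) {
    # ratio change dr: YFP scales by sqrt(1 + dr/100), CFP by its inverse;
    # arbor pixels sit on the same background pedestal as the rest of the
    # field, as in a real image
    s_d <- sqrt(1 + dr[f] / 100)
    cfp[, , f][dend] <- spec$background + spec$baseline_cfp / s_d * bleach[f]
    yfp[, , f][dend] <- spec$background + spec$baseline_yfp * s_d * bleach[f]
    if (any(soma)) {
      s_s <- sqrt(1 + dr_soma[f] / 100)
      cfp[, , f][soma] <- spec$background + spec$baseline_cfp / s_s * bleach[f]
      yfp[, , f][soma] <- spec$background + spec$baseline_yfp * s_s * bleach[f]
    }
  }
  if (spec$noise_sd > 0) {
    cfp <- cfp + stats::rnorm(length(cfp), sd = spec$noise_sd)
    yfp <- yfp + stats::rnorm(length(yfp), sd = spec$noise_sd)
    cfp[cfp < 0] <- 0
    yfp[yfp < 0] <- 0
  }
  image_stack_pair(cfp, yfp, ft, protocol = protocol,
                   truth = list(mask = mask, skeleton = skel, dr = dr,
                                dr_soma = dr_soma, soma = soma))
}
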