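#' Parameters for synthetic damselfly attack trajectories
#'
#' Describes a hover-then-dart attack: the damselfly holds position at
#' `hover_distance` from the perching fly (with Gaussian positional jitter),
#' then darts along a straight line toward the fly at the given elevation and
#' azimuth. The approach speed profile is either constant at `peak_speed` or
#' an accelerating profile — a Gaussian speed bump over a base speed,
#' peaking `peak_time_before_contact` ms before the event end — mimicking
#' attacks whose speed peaks shortly before contact. Independent Gaussian
#' noise per coordinate per frame emulates digitization jitter.
#'
#' @param hover_distance hover distance from the fly, mm.
#' @param hover_duration hover duration, ms.
#' @param hover_jitter_sd positional jitter during the hover, mm.
#' @param profile `"constant_speed"` or `"accelerating"`.
#' @param peak_speed peak approach speed, m/s.
#' @param peak_time_before_contact time of peak speed before the event end,
#'   ms (accelerating profile only).
#' @param base_speed_frac accelerating profile's base speed as a fraction of
#'   `peak_speed`.
#' @param bump_width Gaussian speed-bump width (sd), ms.
#' @param approach_elevation,approach_azimuth attack direction, degrees
#'   (fly-centred frame: +x = wall normal, +z = up).
#' @param digitization_noise_sd per-coordinate tracking noise, mm.
#' @param frame_rate frames per second.
#' @param body_length_mm damselfly head-to-tail length, mm.
#' @param onset_ramp_ms smooth sinusoidal acceleration ramp from the hover to
#'   the approach profile at dart onset, ms (an instantaneous speed step
#'   would be unphysical).
#' @return Object of class `attack_gen_params`.
#' @export
attack_gen_params <- function(hover_distance = 30, hover_duration = 100,
                              hover_jitter_sd = 0.2,
                              profile = c("accelerating", "constant_speed"),
                              peak_speed = 0.25,
                              peak_time_before_contact = 30,
                              base_speed_frac = 0.35, bump_width = 25,
                              approach_elevation = 0, approach_azimuth = 0,
                              digitization_noise_sd = 0.1, frame_rate = 1000,
                              body_length_mm = 25, onset_ramp_ms = 60) {
  profile <- match.arg(profile)
  stopifnot(hover_distance > 0, peak_speed > 0, digitization_noise_sd >= 0,
            hover_jitter_sd >= 0, frame_rate > 0, bump_width > 0,
            base_speed_frac > 0, base_speed_frac <= 1)
  structure(as.list(environment()), class = "attack_gen_params")
}

approach_speed_fun <- function(params) {
  if (params$profile == "constant_speed") {
    function(tau_s) rep(params$peak_speed, length(tau_s))
  } else {
    base <- params$base_speed_frac * params$peak_speed
    tpk <- params$peak_time_before_contact / 1000
    w <- params$bump_width / 1000
    function(tau_s) {
      base + (params$peak_speed - base) * exp(-((tau_s - tpk)^2) / (2 * w^2))
    }
  }
}

#' Generate one synthetic attack trajectory
#'
#' @param params an [attack_gen_params()].
#' @param outcome `"capture"` (approach runs to grab range) or `"escape"`
#'   (approach truncated at the fly's escape distance).
#' @param end_distance damselfly-to-fly distance (mm) at the event end;
#'   defaults to 2 mm for captures and 4 mm for escapes (just beyond the
#'   close-approach grab range).
#' @param seed RNG seed (NULL = use the current RNG state).
#' @return A [tracked_trajectory()] whose `"truth"` attribute records the
#'   programmed ground truth: `peak_speed`, `time_of_peak_speed_ms`,
#'   `elevation`, `azimuth`, `end_distance`, `approach_duration_ms` and
#'   `dart_onset_frame`.
#' @export
gen_attack <- function(params = attack_gen_params(),
                       outcome = c("capture", "escape"),
                       end_distance = NULL, seed = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(params, "attack_gen_params"))
  if (!is.null(seed)) set.seed(seed)
  end_distance <- end_distance %||% if (outcome == "capture") 2 else 4
  approach_dist <- params$hover_distance - end_distance
  if (approach_dist <= 0) stop("end_distance must be below hover_distance")
  dt <- 1 / params$frame_rate
  sfun <- approach_speed_fun(params)
  t_ramp <- params$onset_ramp_ms / 1000
  ramp_f <- function(t_since_dart) {
    ifelse(t_since_dart <= 0, 0,
           ifelse(t_since_dart >= t_ramp, 1,
                  sin(pi * t_since_dart / (2 * t_ramp))^2))
  }

  # Integrate the speed profile backwards from the event end (midpoint rule
  # per frame). The onset ramp is anchored at dart onset, i.e. at
  # time-before-end T = m * dt, so the covered distance is monotone in m:
  # take the smallest frame count m whose self-consistent schedule spans the
  # approach distance.
  frame_steps <- function(m) { # mm travelled per frame, frame 1 = event end
    tau_mid <- (seq_len(m) - 0.5) * dt
    v <- sfun(tau_mid)
    if (t_ramp > 0) v <- v * ramp_f(m * dt - tau_mid)
    v * dt * 1000
  }
  base_speed <- if (params$profile == "constant_speed") params$peak_speed else
    params$base_speed_frac * params$peak_speed
  m_cap <- ceiling(approach_dist / (base_speed * 1000 * dt)) +
    ceiling(t_ramp / dt) + 10L
  unramped <- sfun((seq_len(m_cap) - 0.5) * dt) * dt * 1000
  m0 <- which(cumsum(unramped) >= approach_dist)[1] # no-ramp lower bound
  if (is.na(m0)) m0 <- m_cap
  m <- m0
  while (sum(frame_steps(m)) < approach_dist) {
    m <- m + 1L
    if (m > m_cap + ceiling(t_ramp / dt)) stop("approach does not terminate")
  }
  Ds <- cumsum(frame_steps(m))
  duration_ms <- m * dt * 1000
  if (params$profile == "accelerating" &&
      params$peak_time_before_contact >= duration_ms) {
    stop("peak_time_before_contact lies beyond the approach duration")
  }
  # frame j = 1..m sits (m - j) * dt before the event end
  tau <- (m - seq_len(m)) * dt
  dist_seq <- end_distance + c(Ds[(m - 1):1], 0)
  if (m == 1) dist_seq <- end_distance

  speeds <- sfun(tau) * (if (t_ramp > 0) ramp_f(m * dt - tau) else 1)
  i_pk <- max(which(speeds == max(speeds))) # tie -> latest frame
  truth <- list(peak_speed = speeds[i_pk],
                time_of_peak_speed_ms = -tau[i_pk] * 1000,
                elevation = params$approach_elevation,
                azimuth = params$approach_azimuth,
                end_distance = end_distance,
                approach_duration_ms = duration_ms,
                profile = params$profile)

  e <- deg2rad(params$approach_elevation)
  a <- deg2rad(params$approach_azimuth)
  u <- c(cos(e) * cos(a), cos(e) * sin(a), sin(e))

  n_h <- max(0L, round(params$hover_duration / 1000 * params$frame_rate))
  d_all <- c(rep(params$hover_distance, n_h), dist_seq)
  n <- length(d_all)
  head <- outer(d_all, u)
  if (n_h > 0 && params$hover_jitter_sd > 0) {
    head[seq_len(n_h), ] <- head[seq_len(n_h), ] +
      matrix(stats::rnorm(3 * n_h, 0, params$hover_jitter_sd), n_h, 3)
  }
  tail <- head + matrix(params$body_length_mm * u, n, 3, byrow = TRUE)
  fly <- matrix(0, n, 3)
  if (params$digitization_noise_sd > 0) {
    noise <- function(k) matrix(stats::rnorm(3 * k, 0,
                                             params$digitization_noise_sd),
                                k, 3)
    head <- head + noise(n)
    tail <- tail + noise(n)
    fly <- fly + noise(n)
  }
  truth$dart_onset_frame <- n_h + 1L
  traj <- tracked_trajectory(head, tail, fly, frame_rate = params$frame_rate,
                             outcome = outcome, end_frame = n)
  attr(traj, "truth") <- truth
  traj
}

#' Parameters for synthetic escape ethograms
#'
#' Per fly: take-off is Bernoulli; the reaction time (stimulus onset to wing
#' raise) is Gaussian; the take-off mode is Bernoulli with the short-mode
#' weight; the sequence duration is log-normal with mode-specific
#' parameters; the escape time is reaction time plus duration. Silencing the
#' giant fibre is emulated by dropping the short-mode weight toward zero
#' while leaving the reaction-time distribution untouched.
#'
#' @param takeoff_prob probability a fly takes off.
#' @param reaction_mean,reaction_sd reaction-time distribution, ms.
#' @param short_mode_weight probability a take-off uses the short mode.
#' @param short_meanlog,short_sdlog log-normal duration parameters for the
#'   short mode (ms scale).
#' @param long_meanlog,long_sdlog log-normal duration parameters for the
#'   long mode.
#' @param rv_ms stimulus size-to-speed ratio recorded in the output.
#' @return Object of class `etho_gen_params`.
#' @export
etho_gen_params <- function(takeoff_prob = 0.85, reaction_mean = 95,
                            reaction_sd = 10, short_mode_weight = 0.7,
                            short_meanlog = log(4.5), short_sdlog = 0.15,
                            long_meanlog = log(15), long_sdlog = 0.25,
                            rv_ms = 10) {
  stopifnot(takeoff_prob >= 0, takeoff_prob <= 1,
            short_mode_weight >= 0, short_mode_weight <= 1,
            reaction_sd >= 0, short_sdlog > 0, long_sdlog > 0)
  structure(as.list(environment()), class = "etho_gen_params")
}

#' Generate synthetic escape sequences
#'
#' @param params an [etho_gen_params()].
#' @param n number of flies.
#' @param genotype genotype label for the output table.
#' @param seed RNG seed (NULL = current RNG state).
#' @return An [escape_sequences()] table with a `"truth"` attribute recording
#'   the per-fly drawn mode and the generating parameters.
#' @export
gen_ethograms <- function(params = etho_gen_params(), n, genotype = "control",
                          seed = NULL) {
  stopifnot(inherits(params, "etho_gen_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  took <- stats::runif(n) < params$takeoff_prob
  reaction <- pmax(stats::rnorm(n, params$reaction_mean, params$reaction_sd),
                   0.1)
  short <- stats::runif(n) < params$short_mode_weight
  dur <- ifelse(short,
                stats::rlnorm(n, params$short_meanlog, params$short_sdlog),
                stats::rlnorm(n, params$long_meanlog, params$long_sdlog))
  wing <- ifelse(took, reaction, NA_real_)
  legs <- ifelse(took, reaction + dur, NA_real_)
  out <- escape_sequences(fly_id = sprintf("%s_%04d", genotype, seq_len(n)),
                          genotype = genotype, rv_ms = params$rv_ms,
                          took_off = took, wing_raise_ms = wing,
                          legs_leave_ms = legs)
  attr(out, "truth") <- list(params = params, mode_short = short & took,
                             duration_ms = ifelse(took, dur, NA_real_))
  out
}

#' Parameters for synthetic competition trials
#'
#' Eaten counts per group per trial are binomial draws:
#' `n_a_eaten ~ Binomial(n_per_group, p_a)` and likewise for group b,
#' emulating end-of-trial counts from an arena stocked with `n_per_group`
#' flies of each group.
#'
#' @param n_trials number of trials.
#' @param n_per_group flies released per group per trial.
#' @param p_a,p_b per-fly consumption probability for groups a and b.
#' @param group_a,group_b group labels (group a first in the index
#'   numerator).
#' @param match_type `"PCI"` or `"WCB"`.
#' @return Object of class `trial_gen_params`.
#' @export
trial_gen_params <- function(n_trials = 15, n_per_group = 100,
                             p_a = 0.3, p_b = 0.15,
                             group_a = "silenced", group_b = "control",
                             match_type = c("PCI", "WCB")) {
  match_type <- match.arg(match_type)
  stopifnot(n_trials >= 1, n_per_group >= 1,
            p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  structure(as.list(environment()), class = "trial_gen_params")
}

#' Generate synthetic competition trials
#'
#' @param params a [trial_gen_params()].
#' @param seed RNG seed (NULL = current RNG state).
#' @return Data frame in the competition-trial dialect
#'   (`trial_id,group_a,group_b,n_a_eaten,n_b_eaten,match_type`) plus the
#'   derived `index` column; generating parameters in the `"truth"`
#'   attribute.
#' @export
gen_trials <- function(params = trial_gen_params(), seed = NULL) {
  stopifnot(inherits(params, "trial_gen_params"))
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rbinom(params$n_trials, params$n_per_group, params$p_a)
  b <- stats::rbinom(params$n_trials, params$n_per_group, params$p_b)
  out <- data.frame(trial_id = sprintf("trial_%03d", seq_len(params$n_trials)),
                    group_a = params$group_a, group_b = params$group_b,
                    n_a_eaten = a, n_b_eaten = b,
                    match_type = params$match_type)
  out$index <- consumption_index(a, b)
  attr(out, "truth") <- list(params = params)
  out
}
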