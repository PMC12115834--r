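default_config <- function() {
  list(
    name = "unnamed",
    seed = 1,
    boundary_ms = 7,
    head_width_mm = 2.2, # from the 40 deg <-> ~3 mm correspondence
    speed_split_threshold = 0.167,
    stimulus = list(r_over_v_ms = 10, theta_onset_deg = 10,
                    theta_max_deg = 90),
    smoothing = list(butterworth_order = 2, butterworth_cutoff_hz = 30,
                     savgol_window = 11, savgol_polyorder = 3),
    ethograms = list(
      n = list(control = 80, silenced = 29),
      control = list(takeoff_prob = 0.85, reaction_mean_ms = 95,
                     reaction_sd_ms = 10, short_mode_weight = 0.7,
                     short_meanlog = 1.5041, short_sdlog = 0.15,
                     long_meanlog = 2.7081, long_sdlog = 0.25),
      silenced = list(takeoff_prob = 0.55, reaction_mean_ms = 95,
                      reaction_sd_ms = 10, short_mode_weight = 0.02,
                      short_meanlog = 1.5041, short_sdlog = 0.15,
                      long_meanlog = 2.7081, long_sdlog = 0.25)),
    trials = list(n_trials = 15, n_per_group = 100,
                  p_eaten = list(control = 0.15, silenced = 0.30)),
    attacks = list(
      n_events = list(control = 100, silenced = 100),
      speed_meanlog = -1.8326, speed_sdlog = 0.45,
      speed_min = 0.06, speed_max = 0.6,
      # capture probability is logistic in peak speed; silencing flattens the
      # speed dependence (slope 0) rather than shifting it
      capture_model = list(intercept = list(control = -2.5, silenced = 0.2),
                           slope = list(control = 25, silenced = 0),
                           ref_speed = 0.167),
      end_distance_mm = list(capture_control = 3.4, capture_silenced = 1.8,
                             escape = 4.2),
      elevation_mean = 10, elevation_sd = 8,
      azimuth_mean = 45, azimuth_sd = 25,
      hover_distance = 30, hover_duration = 100, hover_jitter_sd = 0.2,
      base_speed_frac = 0.35, bump_width = 25,
      peak_time_before_contact = 30, onset_ramp_ms = 60,
      digitization_noise_sd = 0.1, frame_rate = 1000)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate (and default-fill) a run configuration
#'
#' Merges a user configuration — typically parsed from a scenario YAML —
#' over the package defaults and checks every numeric field. Validation
#' aggregates problems instead of failing on the first one; on failure the
#' error message lists every offending field with its reason (condition
#' class `loomstrike_config_error`).
#'
#' @param cfg named list (possibly partial) of configuration values, or a
#'   path to a YAML file.
#' @return The validated, default-filled configuration (class `run_config`).
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg) && length(cfg) == 1) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  filled <- setdiff(c("boundary_ms", "head_width_mm"), names(cfg))
  if (length(filled)) {
    message(sprintf("using default %s",
                    paste(vapply(filled, function(f)
                      sprintf("%s = %g", f, default_config()[[f]]), ""),
                      collapse = ", ")))
  }
  cfg <- merge_config(default_config(), cfg)
  errs <- character(0)
  chk <- function(ok, path, why) {
    if (!isTRUE(ok)) errs <<- c(errs, sprintf("%s: %s", path, why))
  }
  chk(cfg$boundary_ms > 0, "boundary_ms", "must be > 0")
  chk(cfg$head_width_mm > 0, "head_width_mm", "must be > 0")
  chk(cfg$speed_split_threshold > 0, "speed_split_threshold", "must be > 0")
  st <- cfg$stimulus
  chk(st$r_over_v_ms > 0, "stimulus.r_over_v_ms", "must be > 0")
  chk(st$theta_onset_deg > 0 && st$theta_onset_deg < st$theta_max_deg &&
        st$theta_max_deg <= 180, "stimulus.theta_onset_deg",
      "need 0 < onset < max <= 180")
  sm <- cfg$smoothing
  chk(sm$savgol_window %% 2 == 1, "smoothing.savgol_window", "must be odd")
  chk(sm$savgol_window > sm$savgol_polyorder, "smoothing.savgol_window",
      "must exceed savgol_polyorder")
  chk(sm$butterworth_order >= 1, "smoothing.butterworth_order", "must be >= 1")
  chk(sm$butterworth_cutoff_hz > 0 &&
        sm$butterworth_cutoff_hz < cfg$attacks$frame_rate / 2,
      "smoothing.butterworth_cutoff_hz", "must lie in (0, frame_rate/2)")
  for (g in c("control", "silenced")) {
    e <- cfg$ethograms[[g]]
    chk(e$takeoff_prob >= 0 && e$takeoff_prob <= 1,
        sprintf("ethograms.%s.takeoff_prob", g), "must be in [0, 1]")
    chk(e$short_mode_weight >= 0 && e$short_mode_weight <= 1,
        sprintf("ethograms.%s.short_mode_weight", g), "must be in [0, 1]")
    p <- cfg$trials$p_eaten[[g]]
    chk(p >= 0 && p <= 1, sprintf("trials.p_eaten.%s", g),
        "must be in [0, 1]")
  }
  chk(cfg$trials$n_trials >= 2, "trials.n_trials", "must be >= 2")
  chk(cfg$attacks$hover_distance >
        max(unlist(cfg$attacks$end_distance_mm)),
      "attacks.hover_distance", "must exceed every end distance")
  if (length(errs)) {
    stop(structure(
      class = c("loomstrike_config_error", "error", "condition"),
      list(message = paste0("invalid configuration:\n  ",
                            paste(errs, collapse = "\n  ")),
           call = sys.call(-1), errors = errs)))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Load a bundled scenario configuration
#'
#' Two scenarios ship with the package: `"null_scenario"` (no genotype
#' effect anywhere — for calibration) and `"silencing_phenotype"` (giant-fibre
#' silencing removes the short take-off mode, halves the escape proportion
#' and raises consumption, with reaction times untouched).
#'
#' @param name scenario name or a path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_scenario <- function(name = c("silencing_phenotype", "null_scenario")) {
  if (file.exists(name[1])) return(validate_config(name[1]))
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "loomstrike", mustWork = TRUE)
  validate_config(path)
}

draw_truncnorm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

simulate_attack_events <- function(cfg, genotype, seed) {
  set.seed(seed)
  at <- cfg$attacks
  n <- at$n_events[[genotype]]
  speeds <- pmin(pmax(stats::rlnorm(n, at$speed_meanlog, at$speed_sdlog),
                      at$speed_min), at$speed_max)
  cm <- at$capture_model
  p_cap <- stats::plogis(cm$intercept[[genotype]] +
                           cm$slope[[genotype]] * (speeds - cm$ref_speed))
  captured <- stats::runif(n) < p_cap
  elev <- draw_truncnorm(n, at$elevation_mean, at$elevation_sd, -80, 80)
  azim <- draw_truncnorm(n, at$azimuth_mean, at$azimuth_sd, 0, 180)
  sm <- smoothing_params(cfg$smoothing$butterworth_order,
                         cfg$smoothing$butterworth_cutoff_hz,
                         cfg$smoothing$savgol_window,
                         cfg$smoothing$savgol_polyorder)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    outcome <- if (captured[i]) "capture" else "escape"
    end_d <- if (captured[i]) {
      at$end_distance_mm[[paste0("capture_", genotype)]]
    } else {
      at$end_distance_mm$escape
    }
    params <- attack_gen_params(
      hover_distance = at$hover_distance, hover_duration = at$hover_duration,
      hover_jitter_sd = at$hover_jitter_sd,
      profile = if (captured[i]) "accelerating" else "constant_speed",
      peak_speed = speeds[i],
      peak_time_before_contact = at$peak_time_before_contact,
      base_speed_frac = at$base_speed_frac, bump_width = at$bump_width,
      onset_ramp_ms = at$onset_ramp_ms,
      approach_elevation = elev[i], approach_azimuth = azim[i],
      digitization_noise_sd = at$digitization_noise_sd,
      frame_rate = at$frame_rate)
    traj <- gen_attack(params, outcome = outcome, end_distance = end_d)
    kin <- attack_kinematics(traj, smoothing = sm,
                             head_width = cfg$head_width_mm)
    s <- kin$summary
    rows[[i]] <- data.frame(
      genotype = genotype, outcome = outcome,
      true_peak_speed = attr(traj, "truth")$peak_speed,
      peak_speed = s$peak_speed, peak_accel = s$peak_accel,
      time_of_peak_speed_ms = s$time_of_peak_speed_ms,
      mean_elevation = s$mean_elevation, mean_azimuth = s$mean_azimuth,
      angular_size_at_end_deg = s$angular_size_at_end_deg)
  }
  do.call(rbind, rows)
}

#' Run the full simulated analysis pipeline
#'
#' Generates a complete synthetic study under a scenario configuration and
#' runs every analysis stage on it: looming-assay ethograms (take-off rates,
#' short-mode percentages, mixture mode-boundary estimate, reaction/escape
#' timing comparison, escape-before-contact fractions), competition trials
#' (prey consumption index with one-sample t-test), and attack kinematics
#' for simulated predation events (escape proportions with Wilson intervals,
#' slow/fast speed split, angular sizes at the event end, and ANOVA + Tukey
#' tests on mean approach angles). Deterministic given the seed.
#'
#' @param cfg a validated `run_config` (see [validate_config()],
#'   [load_scenario()]).
#' @param seed master seed; substreams are derived with [substream_seed()].
#' @param out_dir optional directory: writes `results.json`, `events.csv`,
#'   `ethograms.csv` and `trials.csv`.
#' @return A nested report list, keyed by analysis name.
#' @export
run_full_analysis <- function(cfg = load_scenario("silencing_phenotype"),
                              seed = cfg$seed, out_dir = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  stim <- loom_stimulus(cfg$stimulus$r_over_v_ms,
                        theta_onset = cfg$stimulus$theta_onset_deg,
                        theta_max = cfg$stimulus$theta_max_deg)

  etho <- list()
  seqs <- list()
  for (i in seq_along(c("control", "silenced"))) {
    g <- c("control", "silenced")[i]
    e <- cfg$ethograms[[g]]
    p <- etho_gen_params(takeoff_prob = e$takeoff_prob,
                         reaction_mean = e$reaction_mean_ms,
                         reaction_sd = e$reaction_sd_ms,
                         short_mode_weight = e$short_mode_weight,
                         short_meanlog = e$short_meanlog,
                         short_sdlog = e$short_sdlog,
                         long_meanlog = e$long_meanlog,
                         long_sdlog = e$long_sdlog,
                         rv_ms = cfg$stimulus$r_over_v_ms)
    seqs[[g]] <- gen_ethograms(p, n = cfg$ethograms$n[[g]], genotype = g,
                               seed = substream_seed(seed, i))
    etho[[g]] <- list(
      takeoff_rate = takeoff_rate(seqs[[g]]),
      short_mode = short_mode_percentage(seqs[[g]], cfg$boundary_ms),
      escaped_before_contact =
        fraction_escaped_before_contact(seqs[[g]], stim,
                                        denominator = "responders"))
  }
  pooled <- rbind(as.data.frame(seqs$control), as.data.frame(seqs$silenced))
  pooled_dur <- pooled$legs_leave_ms[pooled$took_off] -
    pooled$wing_raise_ms[pooled$took_off]
  boundary_fit <- tryCatch(estimate_mode_boundary(pooled_dur),
                           loomstrike_unimodal_error = function(e) NULL,
                           error = function(e) NULL)
  timing <- timing_summaries(seqs$control, seqs$silenced,
                             labels = c("control", "silenced"))

  trials <- gen_trials(
    trial_gen_params(n_trials = cfg$trials$n_trials,
                     n_per_group = cfg$trials$n_per_group,
                     p_a = cfg$trials$p_eaten$silenced,
                     p_b = cfg$trials$p_eaten$control),
    seed = substream_seed(seed, 3))
  pci_sum <- index_summary(trials$index)

  events <- rbind(
    simulate_attack_events(cfg, "control", substream_seed(seed, 4)),
    simulate_attack_events(cfg, "silenced", substream_seed(seed, 5)))
  esc_prop <- lapply(split(events, events$genotype), function(d) {
    k <- sum(d$outcome == "escape")
    ci <- unname(wilson_interval(k, nrow(d)))
    list(proportion = k / nrow(d), k = k, n = nrow(d),
         ci_lo = ci[1], ci_hi = ci[2])
  })
  split_tab <- lapply(split(events, events$genotype), function(d) {
    outcome_split_by_speed(d$peak_speed, d$outcome,
                           cfg$speed_split_threshold)
  })
  grp <- interaction(events$genotype, events$outcome, drop = TRUE)
  # the ANOVA needs every genotype-by-outcome cell populated; small runs may
  # miss one, in which case the comparison is reported as unavailable
  angles <- lapply(list(elevation = events$mean_elevation,
                        azimuth = events$mean_azimuth), function(v) {
    tryCatch(angle_group_test(v, grp), error = function(e) NULL)
  })
  theta_by_group <- lapply(split(events$angular_size_at_end_deg, grp), mean)

  report <- list(
    scenario = cfg$name, seed = seed,
    ethogram = list(
      groups = etho,
      mode_boundary = if (is.null(boundary_fit)) NULL else
        list(boundary_ms = boundary_fit$boundary_ms,
             method = boundary_fit$method),
      timing = list(
        reaction_time = list(p = timing$reaction_time$p,
                             t = timing$reaction_time$t),
        escape_time = list(p = timing$escape_time$p,
                           t = timing$escape_time$t))),
    competition = list(
      pci = list(mean = pci_sum$mean, sem = pci_sum$sem,
                 n_trials = pci_sum$n_trials, t = pci_sum$t, p = pci_sum$p)),
    kinematics = list(
      escape_proportion = esc_prop,
      speed_split = split_tab,
      angle_anova = list(
        elevation = list(f = angles$elevation$f, p = angles$elevation$p),
        azimuth = list(f = angles$azimuth$f, p = angles$azimuth$p)),
      mean_angular_size_at_end_deg = theta_by_group))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(pooled, file.path(out_dir, "ethograms.csv"),
                     row.names = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
  }
  attr(report, "events") <- events
  attr(report, "sequences") <- seqs
  report
}
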