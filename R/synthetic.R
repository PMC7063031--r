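# Synthetic multi-participant sEMG generator.
#
# Emulates the structure of an armband recording protocol: P participants
# x G gestures x 8 cycles of 5 s held contractions at 1 kHz over 10
# channels. Each channel carries band-limited (20-450 Hz) Gaussian noise
# whose amplitude follows a gesture-specific activation profile -- a
# circular Gaussian bump over the channel axis, mimicking the muscle
# closest to the active electrode. Participants differ by an integer
# circular rotation of the channels (armband donning position), a
# per-channel log-uniform gain (electrode contact quality) and an additive
# noise floor. Within-participant recognition is designed to be easy;
# cross-participant recognition is hard because rotation remaps channels.

# evaluate with a temporary RNG state derived from `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic dataset configuration
#'
#' Defaults describe the emulated recording protocol: 8 participants, 5
#' gestures, 10 channels at 1 kHz, 8 cycles of 5 s holds, amplitude scale
#' 450 (arbitrary device units). Domain-shift defaults: participant `p`
#' receives channel rotation `(p - 1) mod 4` (offsets 0-3, so rotations of
#' two or more channels occur), per-channel gains log-uniform in
#' `gain_range` and a noise floor with SD drawn from `noise_sd_range`
#' (fractions of `sigma_base`).
#'
#' @param participants,gestures,channels,fs,cycle_s,cycles protocol shape.
#' @param sigma_base overall amplitude scale of the active channel.
#' @param bump_width width (in channels) of the activation bump.
#' @param activation_floor baseline activation of inactive channels.
#' @param rotation_offsets integer rotations per participant, or `NULL`
#'   for the default deterministic assignment.
#' @param gain_range per-channel gain range (log-uniform).
#' @param noise_sd_range additive noise floor SD range, as a fraction of
#'   `sigma_base`.
#' @param seed integer seed controlling all randomness.
#' @export
synth_config <- function(participants = 8, gestures = 5, channels = 10,
                         fs = 1000, cycle_s = 5, cycles = 8,
                         sigma_base = 450, bump_width = 1.0,
                         activation_floor = 0.15,
                         rotation_offsets = NULL,
                         gain_range = c(0.75, 1.33),
                         noise_sd_range = c(0.02, 0.08),
                         seed = 1L) {
  .assert(participants >= 2 && gestures >= 2, "need >= 2 participants and gestures")
  if (is.null(rotation_offsets)) {
    # zero-mean symmetric donning variability: rotations up to +/- 2
    # channels, so some participants are rotated by >= 2
    rotation_offsets <- rep(c(0L, 1L, -1L, 2L, -2L, 1L, -1L, 0L),
                            length.out = participants)
  }
  .assert(length(rotation_offsets) == participants, "one rotation per participant")
  structure(list(participants = participants, gestures = gestures,
                 channels = channels, fs = fs, cycle_s = cycle_s,
                 cycles = cycles, sigma_base = sigma_base,
                 bump_width = bump_width, activation_floor = activation_floor,
                 rotation_offsets = as.integer(rotation_offsets),
                 gain_range = gain_range, noise_sd_range = noise_sd_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Channel on which a gesture's activation bump is centred (before any
#' participant rotation)
#' @param config a [synth_config()].
#' @param gesture gesture id, `0 .. gestures - 1`.
#' @export
gesture_center <- function(config, gesture) {
  1 + round(gesture * config$channels / config$gestures)
}

# circular activation profile over channels for one gesture
.activation_profile <- function(config, gesture) {
  mu <- gesture_center(config, gesture)
  ch <- seq_len(config$channels)
  d <- pmin(abs(ch - mu), config$channels - abs(ch - mu))
  config$activation_floor +
    (1 - config$activation_floor) * exp(-d^2 / (2 * config$bump_width^2))
}

#' Generate the synthetic recordings
#'
#' @param config a [synth_config()].
#' @return list of [emg_recording()] objects, one per
#'   (participant, gesture, cycle), deterministic given `config$seed`.
#' @export
generate_recordings <- function(config = synth_config()) {
  cfg <- config
  filt <- butter_bandpass(20, 450, cfg$fs, 4)
  .with_seed(cfg$seed, {
    # participant-level domain parameters
    gains <- matrix(exp(stats::runif(cfg$participants * cfg$channels,
                                     log(cfg$gain_range[1]), log(cfg$gain_range[2]))),
                    nrow = cfg$participants)
    noise_sd <- stats::runif(cfg$participants, cfg$noise_sd_range[1],
                             cfg$noise_sd_range[2]) * cfg$sigma_base
    s <- round(cfg$cycle_s * cfg$fs)
    recs <- vector("list", cfg$participants * cfg$gestures * cfg$cycles)
    k <- 0
    for (p in seq_len(cfg$participants)) {
      rot <- cfg$rotation_offsets[p]
      for (g in seq_len(cfg$gestures) - 1L) {
        prof <- .activation_profile(cfg, g)
        # apply the circular channel rotation of this participant
        idx <- ((seq_len(cfg$channels) - 1 - rot) %% cfg$channels) + 1
        prof_p <- prof[idx] * gains[p, ]
        for (cyc in seq_len(cfg$cycles)) {
          cyc_gain <- exp(stats::rnorm(1, 0, 0.1))
          sig <- matrix(0, cfg$channels, s)
          if (cfg$sigma_base > 0) {
            e <- matrix(stats::rnorm(cfg$channels * s), cfg$channels, s)
            e <- filter_signal(e, filt)
            # renormalise so the activation profile maps directly to RMS
            e <- e / pmax(sqrt(rowMeans(e^2)), .EPS)
            noise <- matrix(stats::rnorm(cfg$channels * s, sd = noise_sd[p]),
                            cfg$channels, s)
            sig <- cfg$sigma_base * cyc_gain * prof_p * e + noise
          }
          k <- k + 1
          recs[[k]] <- emg_recording(sig, p, g, cyc, fs = cfg$fs)
        }
      }
    }
    recs
  })
}

#' Generate a preprocessed synthetic dataset
#'
#' Convenience wrapper: [generate_recordings()] followed by
#' [preprocess_recordings()].
#'
#' @param config a [synth_config()].
#' @param ... passed to [preprocess_recordings()].
#' @export
generate_dataset <- function(config = synth_config(), ...) {
  preprocess_recordings(generate_recordings(config), ...)
}

#' Write a synthetic dataset as CSV signal files plus a JSON manifest
#'
#' Emits the on-disk format consumed by [load_dataset()].
#'
#' @param config a [synth_config()].
#' @param dir output directory.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_recordings(config)
  man <- data.frame(file = character(0), participant = integer(0),
                    gesture = integer(0), cycle = integer(0))
  for (rec in recs) {
    fn <- sprintf("p%02d_g%02d_c%02d.csv", rec$participant, rec$gesture, rec$cycle)
    utils::write.table(rec$signal, file.path(dir, fn), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    man <- rbind(man, data.frame(file = fn, participant = rec$participant,
                                 gesture = rec$gesture, cycle = rec$cycle))
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"), digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' Generate a pure Gaussian-noise window
#'
#' A 10 x 151 window of iid zero-mean Gaussian samples, used to probe what
#' a trained network "sees" in matched-scale noise.
#'
#' @param sigma noise standard deviation (default 450, the amplitude scale
#'   of the recordings).
#' @param seed integer seed.
#' @param channels,window_len window shape.
#' @export
generate_noise_window <- function(sigma = 450, seed = 1L, channels = 10,
                                  window_len = 151) {
  data <- .with_seed(seed,
    matrix(stats::rnorm(channels * window_len, 0, sigma), channels, window_len))
  structure(list(data = data, participant = NA_integer_,
                 gesture = NA_integer_, cycle = NA_integer_),
            class = "emg_window")
}
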