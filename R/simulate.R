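#' Configuration for the synthetic blendshape-segment generator
#'
#' The generator emulates the statistical structure of a smile-annotation
#' study: short fixed-length segments, a minority of smile events, a smooth
#' unimodal mouthSmile pulse during smiles, correlated but less
#' discriminative cheekSquint activity, bounded low-amplitude noise during
#' neutral segments, and segments nested within participants.
#'
#' The mouthSmile amplitude ranges of the two classes are disjoint by
#' default (neutral at most `neutral_high` = 0.30, smile peaks at least
#' `smile_low` = 0.60), so a threshold classifier on the training half must
#' separate the classes perfectly and recover a threshold inside the gap.
#' The cheekSquint channels are an attenuated, noisier copy of the same
#' event (`cheek_attenuation`, `cheek_sd`), calibrated so that a
#' cheekSquint-only classifier is informative but imperfect
#' (AUC around 0.95-0.97).
#'
#' @param n_segments Number of 5-s segments (default 158).
#' @param p_smile Probability that a segment is a smile event
#'   (default 0.354, the smile share implied by a 28-of-79 test half).
#' @param n_participants Number of participants; segments are assigned
#'   round-robin (default 9).
#' @param fps Frames per second (default 10).
#' @param duration_s Segment duration in seconds (default 5).
#' @param smile_low,smile_high Range of the mouthSmile peak amplitude in
#'   smile segments (default 0.60-0.95).
#' @param neutral_low,neutral_high Range of mouthSmile noise in neutral
#'   segments (default 0.00-0.30).
#' @param cheek_attenuation Multiplier applied to the smile pulse on the
#'   cheekSquint channels (default 0.55).
#' @param cheek_sd Standard deviation of per-frame Gaussian noise on the
#'   cheekSquint channels (default 0.12).
#' @param p_one_sided Probability that a smile expresses on one side of the
#'   face only (default 0.2).
#' @param jitter_sd Standard deviation of per-frame jitter on the active
#'   mouthSmile channels (default 0.02).
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return An object of class `simulation_config`.
#' @seealso [simulate_segments()]
#' @export
simulation_config <- function(n_segments = 158,
                              p_smile = 0.354,
                              n_participants = 9,
                              fps = 10,
                              duration_s = 5,
                              smile_low = 0.60,
                              smile_high = 0.95,
                              neutral_low = 0.00,
                              neutral_high = 0.30,
                              cheek_attenuation = 0.55,
                              cheek_sd = 0.12,
                              p_one_sided = 0.2,
                              jitter_sd = 0.02,
                              seed = 1L) {
  stopifnot(
    length(n_segments) == 1, n_segments >= 1, n_segments == round(n_segments),
    length(n_participants) == 1, n_participants >= 1
  )
  if (p_smile < 0 || p_smile > 1) stop("p_smile must lie in [0, 1]", call. = FALSE)
  if (p_one_sided < 0 || p_one_sided > 1) {
    stop("p_one_sided must lie in [0, 1]", call. = FALSE)
  }
  if (smile_low >= smile_high) stop("smile_low must be < smile_high", call. = FALSE)
  if (neutral_low >= neutral_high) {
    stop("neutral_low must be < neutral_high", call. = FALSE)
  }
  check_fps(fps)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  structure(
    list(
      n_segments = as.integer(n_segments), p_smile = p_smile,
      n_participants = as.integer(n_participants), fps = fps,
      duration_s = duration_s,
      smile_low = smile_low, smile_high = smile_high,
      neutral_low = neutral_low, neutral_high = neutral_high,
      cheek_attenuation = cheek_attenuation, cheek_sd = cheek_sd,
      p_one_sided = p_one_sided, jitter_sd = jitter_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate blendshape segments with ground-truth smile labels
#'
#' Each smile segment contains a trapezoidal pulse (0.5 s rise, 1-3 s
#' plateau, 0.5 s fall, onset uniform within the segment) on the active
#' mouthSmile channel(s), with the peak drawn from the smile amplitude
#' range and small Gaussian jitter; the apex frame is guaranteed to reach
#' the drawn peak so the per-segment maximum stays above the class gap.
#' Neutral segments carry independent bounded noise from the neutral range.
#' cheekSquint channels replay the same event attenuated and noisier.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `frames` (per-frame tibble as in
#'   [read_segments()], with attribute `"fps"`) and `truth`
#'   (tibble `segment_id`, `label` of ground-truth classes).
#' @export
simulate_segments <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_segments
  n_frames <- as.integer(round(config$duration_s * config$fps))
  withr::with_seed(config$seed, {
    ids <- sprintf("seg%03d", seq_len(n))
    participants <- sprintf("P%02d", rep_len(seq_len(config$n_participants), n))
    labels <- rbinom(n, 1L, config$p_smile)
    per_segment <- vector("list", n)
    t <- (seq_len(n_frames) - 1) / config$fps
    for (i in seq_len(n)) {
      if (labels[i] == 1L) {
        peak <- runif(1, config$smile_low, config$smile_high)
        env <- smile_envelope(t, config$duration_s)
        one_sided <- runif(1) < config$p_one_sided
        active <- if (one_sided) sample(c("L", "R"), 1) else c("L", "R")
        mouth <- list(
          L = neutral_series(n_frames, config),
          R = neutral_series(n_frames, config)
        )
        for (side in active) {
          v <- clamp01(peak * env + rnorm(n_frames, 0, config$jitter_sd))
          apex <- which.max(env)
          v[apex] <- max(v[apex], peak)
          mouth[[side]] <- v
        }
        cheek_base <- config$cheek_attenuation * peak * env
        cheek_L <- clamp01(cheek_base + rnorm(n_frames, 0, config$cheek_sd))
        cheek_R <- clamp01(cheek_base + rnorm(n_frames, 0, config$cheek_sd))
      } else {
        mouth <- list(
          L = neutral_series(n_frames, config),
          R = neutral_series(n_frames, config)
        )
        cheek_L <- clamp01(runif(n_frames, config$neutral_low, config$neutral_high) +
                             rnorm(n_frames, 0, config$cheek_sd))
        cheek_R <- clamp01(runif(n_frames, config$neutral_low, config$neutral_high) +
                             rnorm(n_frames, 0, config$cheek_sd))
      }
      per_segment[[i]] <- tibble::tibble(
        segment_id = ids[i],
        participant_id = participants[i],
        frame_index = seq_len(n_frames) - 1L,
        mouthSmile_L = mouth$L,
        mouthSmile_R = mouth$R,
        cheekSquint_L = cheek_L,
        cheekSquint_R = cheek_R
      )
    }
    frames <- dplyr::bind_rows(per_segment)
    attr(frames, "fps") <- config$fps
    list(
      frames = frames,
      truth = tibble::tibble(segment_id = ids, label = as.integer(labels))
    )
  })
}

# trapezoid: 0.5 s rise, 1-3 s plateau, 0.5 s fall, onset uniform in the
# room left by the pulse; returns envelope values in [0, 1] over times t
smile_envelope <- function(t, duration_s, rise = 0.5, fall = 0.5) {
  plateau <- runif(1, 1, min(3, duration_s - rise - fall))
  onset <- runif(1, 0, duration_s - (rise + plateau + fall))
  up <- (t - onset) / rise
  down <- (onset + rise + plateau + fall - t) / fall
  clamp01(pmin(up, 1, down))
}

neutral_series <- function(n_frames, config) {
  runif(n_frames, config$neutral_low, config$neutral_high)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Configuration for the simulated human rater panel
#'
#' Each rater independently copies the ground-truth label of every segment
#' and flips it with a small probability, emulating a panel with high but
#' imperfect agreement. With the default flip probability of 0.016 and five
#' raters on 158 segments, Fleiss' kappa concentrates near 0.91.
#'
#' @param n_raters Number of raters (default 5; odd panels make majority
#'   ties impossible).
#' @param p_flip Per-rater, per-segment probability of recording the wrong
#'   label (default 0.016; must lie in \[0, 0.5)).
#' @param seed Integer seed.
#' @return An object of class `rater_sim_config`.
#' @export
rater_sim_config <- function(n_raters = 5, p_flip = 0.016, seed = 1L) {
  stopifnot(length(n_raters) == 1, n_raters >= 2, n_raters == round(n_raters))
  if (p_flip < 0 || p_flip >= 0.5) {
    stop("p_flip must lie in [0, 0.5)", call. = FALSE)
  }
  structure(
    list(n_raters = as.integer(n_raters), p_flip = p_flip,
         seed = as.integer(seed)),
    class = "rater_sim_config"
  )
}

#' Simulate a multi-rater annotation panel
#'
#' @param truth A tibble `segment_id`, `label` of ground-truth classes.
#' @param config A [rater_sim_config()].
#' @return A ratings tibble: `segment_id` plus one binary column per rater
#'   (`rater_1`, ..., `rater_r`).
#' @seealso [fleiss_kappa()], [majority_vote()]
#' @export
simulate_raters <- function(truth, config = rater_sim_config()) {
  stopifnot(inherits(config, "rater_sim_config"))
  truth <- validate_labels(truth)
  n <- nrow(truth)
  withr::with_seed(config$seed, {
    ratings <- tibble::tibble(segment_id = truth$segment_id)
    for (j in seq_len(config$n_raters)) {
      flip <- runif(n) < config$p_flip
      ratings[[paste0("rater_", j)]] <- ifelse(flip, 1L - truth$label,
                                               truth$label)
    }
    ratings
  })
}
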