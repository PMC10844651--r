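# Synthetic dyads and rater panels with known ground truth.
#
# Movement is generated in joint-angle space: shoulder and elbow angles are
# smooth sums of random sinusoids and limbs are placed by forward kinematics
# with constant bone lengths. That preserves exactly the properties the
# kinematic measures rely on (smoothness, rigid segments, controllable
# leader-follower coupling) without any recorded human data.

#' Configuration for a simulated mirror-game dyad
#'
#' Defaults emulate the stimulus material: 10-s clips at 60 fps (600
#' frames), a follower who mirrors with a 100-300 ms lag in the
#' high-synchrony condition and merely watches (near-still resting posture)
#' in the low-synchrony condition, and leader arm movement built from
#' sinusoids in the 0.1-1.5 Hz band typical of improvised arm movement.
#'
#' @param condition `"high"` (mirroring) or `"low"` (observing).
#' @param duration_s clip length in seconds.
#' @param fps frames per second.
#' @param follower_lag_ms follower reaction lag, milliseconds (high only).
#' @param follower_noise_sd SD of follower joint-angle noise, radians.
#' @param freq_range leader joint-angle frequency band, Hz.
#' @param upper_arm,forearm segment lengths, pixels.
#' @param seed integer RNG seed.
#' @return List of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(condition = c("high", "low"), duration_s = 10,
                            fps = 60, follower_lag_ms = 200,
                            follower_noise_sd = 0.05,
                            freq_range = c(0.1, 1.5),
                            upper_arm = 60, forearm = 50, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(follower_lag_ms >= 0, fps > 0, duration_s > 0,
            abs(fps * duration_s - round(fps * duration_s)) < 1e-9)
  structure(
    list(condition = condition, duration_s = duration_s, fps = fps,
         follower_lag_ms = follower_lag_ms,
         follower_noise_sd = follower_noise_sd, freq_range = freq_range,
         upper_arm = upper_arm, forearm = forearm, seed = seed),
    class = "dyad_sim_config"
  )
}

# smooth random angle process: mean + sum of 3-5 sinusoids in the band
random_angle_process <- function(t, freq_range, mean_angle, amplitude) {
  k <- sample(3:5, 1)
  f <- stats::runif(k, freq_range[1], freq_range[2])
  ph <- stats::runif(k, 0, 2 * pi)
  a <- stats::runif(k, 0.3, 1) * amplitude / sqrt(k)
  th <- rep(mean_angle, length(t))
  for (i in seq_len(k)) th <- th + a[i] * sin(2 * pi * f[i] * t + ph[i])
  th
}

# forward kinematics from neck position and four arm angles (radians,
# measured from straight-down; image y grows downward)
arm_fk <- function(neck_xy, shoulder_w, th_r_ua, th_r_fa, th_l_ua, th_l_fa,
                   L_ua, L_fa) {
  T_ <- nrow(neck_xy)
  coords <- array(0, c(T_, 7, 2))
  coords[, 1, ] <- neck_xy
  coords[, 2, 1] <- neck_xy[, 1] + shoulder_w / 2   # r_shoulder
  coords[, 2, 2] <- neck_xy[, 2]
  coords[, 3, 1] <- neck_xy[, 1] - shoulder_w / 2   # l_shoulder
  coords[, 3, 2] <- neck_xy[, 2]
  place <- function(from, th, L) cbind(from[, 1] + L * sin(th),
                                       from[, 2] + L * cos(th))
  coords[, 4, ] <- place(coords[, 2, , drop = TRUE], th_r_ua, L_ua) # r_elbow
  coords[, 5, ] <- place(coords[, 3, , drop = TRUE], th_l_ua, L_ua) # l_elbow
  coords[, 6, ] <- place(coords[, 4, , drop = TRUE], th_r_fa, L_fa) # r_hand
  coords[, 7, ] <- place(coords[, 5, , drop = TRUE], th_l_fa, L_fa) # l_hand
  coords
}

#' Simulate the leading mover of a dyad
#'
#' The torso (neck, shoulders) carries only small smooth jitter; elbows and
#' wrists are driven by forward kinematics from smooth random joint-angle
#' processes. The generating angle series are attached as the `angles`
#' attribute so a follower can be coupled to them.
#'
#' @param cfg a [dyad_sim_config()].
#' @param centre_x horizontal position of the figure, pixels.
#' @return A [pose_series()] with constant bone lengths.
#' @export
simulate_leader <- function(cfg, centre_x = 200) {
  withr::local_seed(cfg$seed)
  T_ <- as.integer(round(cfg$duration_s * cfg$fps))
  t <- (seq_len(T_) - 1) / cfg$fps
  jitter <- function(amp) amp * sin(2 * pi * stats::runif(1, 0.1, 0.4) * t +
                                    stats::runif(1, 0, 2 * pi))
  neck <- cbind(centre_x + jitter(2), 150 + jitter(2))
  angles <- list(
    r_ua = random_angle_process(t, cfg$freq_range, mean_angle = 0.9, amplitude = 0.9),
    r_fa = random_angle_process(t, cfg$freq_range, mean_angle = 0.4, amplitude = 1.1),
    l_ua = random_angle_process(t, cfg$freq_range, mean_angle = -0.9, amplitude = 0.9),
    l_fa = random_angle_process(t, cfg$freq_range, mean_angle = -0.4, amplitude = 1.1)
  )
  coords <- arm_fk(neck, shoulder_w = 50, angles$r_ua, angles$r_fa,
                   angles$l_ua, angles$l_fa, cfg$upper_arm, cfg$forearm)
  s <- pose_series(coords, matrix(0.95, T_, 7), fps = cfg$fps,
                   person_id = "leader")
  attr(s, "angles") <- angles
  attr(s, "neck") <- neck
  s
}

#' Simulate the second dyad member coupled to a leader
#'
#' High synchrony: the follower plays the mirror game — its joint angles
#' equal the leader's delayed by `follower_lag_ms` plus Gaussian angle
#' noise. Low synchrony: the follower observes, holding a resting posture
#' (arms hanging) with small postural jitter, independent of the leader.
#'
#' @param leader output of [simulate_leader()].
#' @param cfg the same [dyad_sim_config()].
#' @param centre_x horizontal position of the follower (default: leader
#'   offset by +200 px, i.e. standing to the right).
#' @return A [pose_series()].
#' @export
simulate_follower <- function(leader, cfg, centre_x = 400) {
  ang <- attr(leader, "angles")
  if (is.null(ang)) stop_dyadsync("leader must come from simulate_leader()")
  withr::local_seed(child_seed(cfg$seed, 7))
  T_ <- n_frames(leader)
  t <- (seq_len(T_) - 1) / cfg$fps
  lag <- as.integer(round(cfg$follower_lag_ms / 1000 * cfg$fps))
  if (lag >= T_) stop_dyadsync("follower lag must be shorter than the clip")
  jitter <- function(amp) amp * sin(2 * pi * stats::runif(1, 0.1, 0.4) * t +
                                    stats::runif(1, 0, 2 * pi))
  neck <- cbind(centre_x + jitter(2), 150 + jitter(2))
  if (cfg$condition == "high") {
    delay <- function(x) c(rep(x[1], lag), x)[seq_len(T_)]
    noise <- function() if (cfg$follower_noise_sd > 0)
      stats::rnorm(T_, 0, cfg$follower_noise_sd) else 0
    angles <- lapply(ang, function(a) delay(a) + noise())
  } else {
    rest <- function(mean_angle) mean_angle + 0.02 * jitter(1)
    angles <- list(r_ua = rest(0.12), r_fa = rest(0.05),
                   l_ua = rest(-0.12), l_fa = rest(-0.05))
  }
  coords <- arm_fk(neck, shoulder_w = 50, angles$r_ua, angles$r_fa,
                   angles$l_ua, angles$l_fa, cfg$upper_arm, cfg$forearm)
  pose_series(coords, matrix(0.95, T_, 7), fps = cfg$fps,
              person_id = "follower")
}

#' Simulate one dyad recording
#'
#' Convenience wrapper: leader plus coupled follower, packaged as a
#' [dyad_recording()] whose task label follows the condition (high =
#' mirroring, low = observing).
#'
#' @param cfg a [dyad_sim_config()].
#' @param dyad_id,leader_id labels.
#' @return A [dyad_recording()].
#' @export
simulate_dyad <- function(cfg, dyad_id = "sim_dyad", leader_id = "L01") {
  leader <- simulate_leader(cfg)
  follower <- simulate_follower(leader, cfg)
  attr(leader, "angles") <- NULL
  attr(leader, "neck") <- NULL
  dyad_recording(leader, follower, dyad_id = dyad_id, leader_id = leader_id,
                 condition = if (cfg$condition == "high") "mirroring" else "observing")
}

#' Simulate a counterbalanced stimulus pool with kinematic summaries
#'
#' Generates `n_clips` 10-s dyadic clips (the stated stimulus-set design:
#' 198 clips, 85% high synchrony, 16 unique leaders assigned round-robin),
#' computes each clip's measured similarity and predictability, and
#' assigns counterbalanced leader colour/side.
#'
#' @param n_clips number of clips (default 198).
#' @param prop_high proportion of high-synchrony clips (default 0.85).
#' @param n_leaders number of unique leaders (default 16).
#' @param seed integer RNG seed.
#' @param sim_overrides named list of [dyad_sim_config()] fields to override
#'   (e.g. smaller `duration_s` for fast tests).
#' @param keep_clips also return the full keypoint recordings (default
#'   FALSE; the manifest alone is enough for the rating models).
#' @return A list with `manifest` (data frame: clip_id, dyad_id, leader_id,
#'   condition, leader_color, leader_side, measured_similarity,
#'   predictability, coverage) and `clips` (list of recordings).
#' @export
simulate_stimulus_pool <- function(n_clips = 198, prop_high = 0.85,
                                   n_leaders = 16, seed = 1,
                                   sim_overrides = list(),
                                   keep_clips = FALSE) {
  stopifnot(prop_high > 0, prop_high < 1, n_clips >= 1)
  n_high <- as.integer(round(prop_high * n_clips))
  conds <- c(rep("high", n_high), rep("low", n_clips - n_high))
  leaders <- sprintf("L%02d", rep(seq_len(n_leaders), length.out = n_clips))
  rows <- vector("list", n_clips)
  clips <- if (keep_clips) vector("list", n_clips) else NULL
  for (i in seq_len(n_clips)) {
    args <- utils::modifyList(
      list(condition = conds[i], seed = child_seed(seed, i)), sim_overrides)
    cfg <- do.call(dyad_sim_config, args)
    rec <- simulate_dyad(cfg, dyad_id = sprintf("clip%03d", i),
                         leader_id = leaders[i])
    ks <- kinematic_summary(rec, clip_id = sprintf("clip%03d", i))
    rows[[i]] <- data.frame(clip_id = ks$clip_id, dyad_id = rec$dyad_id,
                            leader_id = leaders[i], condition = conds[i],
                            measured_similarity = ks$measured_similarity,
                            predictability = ks$predictability,
                            coverage = ks$coverage,
                            stringsAsFactors = FALSE)
    if (keep_clips) clips[[i]] <- rec
  }
  manifest <- do.call(rbind, rows)
  manifest <- counterbalance_assign(manifest, seed = child_seed(seed, 0))
  list(manifest = manifest, clips = clips)
}

#' Configuration for a simulated rater panel
#'
#' The defaults are the package's "stated world": raters systematically
#' underestimate synchrony (more so for low-synchrony clips), body
#' competence improves accuracy for low synchrony, autistic traits worsen
#' it for high synchrony; enjoyment rises with measured similarity and
#' empathy and falls with entropy (i.e. rises with predictability), and
#' very low enjoyment is more likely with high body perception and less
#' likely for similar movements.
#'
#' Trait slopes are named lists mapping covariate name to true coefficient
#' (on the z-scored covariate scale); unnamed covariates have slope 0.
#'
#' @param n_raters panel size.
#' @param n_clips_per_rater clips rated by each rater (default 50).
#' @param alpha_high,alpha_low true underestimation offsets (slider units).
#' @param slopes_high,slopes_low accuracy-model slopes per condition.
#' @param gamma true inflation-part coefficients (named; `Intercept` is the
#'   logit of the baseline very-low-enjoyment probability).
#' @param delta true continuous-part coefficients (named; `Intercept` on the
#'   11-100 rating scale).
#' @param sigma_high,sigma_low accuracy residual SDs per condition.
#' @param sigma_enjoy continuous-part residual SD.
#' @param tau_participant,tau_clip accuracy random-intercept SDs.
#' @param tau_inflation,tau_enjoy_participant,tau_enjoy_clip hurdle-model
#'   random-intercept SDs.
#' @param trait_cor baseline pairwise trait correlation (default 0.2, with
#'   empathy vs autistic traits at -0.3).
#' @param seed integer RNG seed.
#' @return List of class `rater_sim_config`.
#' @export
rater_sim_config <- function(n_raters = 100, n_clips_per_rater = 50,
                             alpha_high = 26, alpha_low = 37.5,
                             slopes_high = list(autistic_traits = 1.5),
                             slopes_low = list(body_competence = -2.0),
                             gamma = list(Intercept = -1.75,
                                          measured_similarity = -1.0,
                                          body_perception = 1.0),
                             delta = list(Intercept = 50,
                                          measured_similarity = 5,
                                          predictability = -2,
                                          empathy = 3),
                             sigma_high = 10, sigma_low = 12,
                             sigma_enjoy = 12,
                             tau_participant = 6, tau_clip = 3,
                             tau_inflation = 0.5,
                             tau_enjoy_participant = 5, tau_enjoy_clip = 2,
                             trait_cor = 0.2, seed = 1) {
  structure(as.list(environment()), class = "rater_sim_config")
}

TRAITS <- c("extraversion", "self_esteem", "body_perception",
            "body_competence", "empathy", "autistic_traits")

# instrument-scale centres and spreads used to map latent z to raw scores
TRAIT_SCALES <- data.frame(
  trait = TRAITS,
  mean = c(30, 18, 80, 10, 60, 130),
  sd = c(7, 5, 20, 4, 14, 30)
)

trait_covariance <- function(trait_cor) {
  S <- matrix(trait_cor, 6, 6)
  diag(S) <- 1
  i <- match(c("empathy", "autistic_traits"), TRAITS)
  S[i[1], i[2]] <- S[i[2], i[1]] <- -0.3
  S
}

# draw n samples from MVN(0, S) via eigen decomposition (PSD-safe)
rmvnorm0 <- function(n, S) {
  e <- eigen(S, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  matrix(stats::rnorm(n * ncol(S)), n) %*% t(A)
}

#' Simulate a rater panel over a stimulus pool
#'
#' Draws correlated traits for each rater, assigns each rater a random set
#' of clips, and generates the three slider ratings per (rater, clip):
#' the synchrony estimate follows the accuracy model (difference =
#' condition offset + covariate effects + participant and clip intercepts +
#' noise, so the estimate is 100 x similarity minus that difference,
#' clipped to the slider); enjoyment follows the two-part process (a
#' Bernoulli very-low-enjoyment indicator, otherwise a Gaussian on 11-100);
#' reproducibility is generated as a simple similarity-linked Gaussian.
#'
#' All covariate effects are applied to z-scored covariates standardized
#' within the generated panel/trial set, so the serialized ground truth is
#' on exactly the scale the fitting functions report.
#'
#' @param pool manifest data frame from [simulate_stimulus_pool()].
#' @param cfg a [rater_sim_config()].
#' @return A list: `traits` (one row per rater, instrument scales),
#'   `ratings` (long table: participant_id, clip_id, question, value),
#'   `accuracy` (trial table with difference values and covariates, ready
#'   for [fit_accuracy_model()]), `enjoyment` (trial table for
#'   [fit_enjoyment_model()]), `ground_truth` (all true parameter values).
#' @export
simulate_raters <- function(pool, cfg = rater_sim_config()) {
  stopifnot(is.data.frame(pool),
            all(c("clip_id", "condition", "measured_similarity",
                  "predictability") %in% names(pool)))
  if (cfg$n_clips_per_rater > nrow(pool))
    stop_dyadsync("n_clips_per_rater exceeds pool size")
  withr::local_seed(cfg$seed)
  J <- cfg$n_raters
  ids <- sprintf("P%03d", seq_len(J))
  zt <- rmvnorm0(J, trait_covariance(cfg$trait_cor))
  colnames(zt) <- TRAITS
  # standardize within panel so truth scale == fitted scale
  zt <- scale(zt)
  traits_raw <- sweep(sweep(zt, 2, TRAIT_SCALES$sd, `*`), 2,
                      TRAIT_SCALES$mean, `+`)
  traits <- data.frame(participant_id = ids, round(traits_raw, 2))

  trial <- do.call(rbind, lapply(seq_len(J), function(j) {
    idx <- sample(nrow(pool), cfg$n_clips_per_rater)
    data.frame(participant_id = ids[j], pool[idx, ], row.names = NULL)
  }))
  n <- nrow(trial)
  jix <- match(trial$participant_id, ids)
  kix <- match(trial$clip_id, pool$clip_id)
  z_sim <- as.numeric(scale(trial$measured_similarity))
  z_ent <- as.numeric(scale(trial$predictability))
  zcov <- cbind(measured_similarity = z_sim, predictability = z_ent,
                zt[jix, , drop = FALSE])

  slope_vec <- function(slopes) {
    out <- rep(0, ncol(zcov)); names(out) <- colnames(zcov)
    for (nm in names(slopes)) {
      if (!nm %in% names(out)) stop_dyadsync("unknown covariate '", nm, "'")
      out[nm] <- slopes[[nm]]
    }
    out
  }
  # ---- accuracy / synchrony estimates ----
  u <- stats::rnorm(J, 0, cfg$tau_participant)
  v <- stats::rnorm(nrow(pool), 0, cfg$tau_clip)
  high <- trial$condition == "high"
  sh <- slope_vec(cfg$slopes_high); sl <- slope_vec(cfg$slopes_low)
  fx <- ifelse(high,
               cfg$alpha_high + zcov %*% sh,
               cfg$alpha_low + zcov %*% sl)
  noise_sd <- ifelse(high, cfg$sigma_high, cfg$sigma_low)
  difference <- as.numeric(fx) + u[jix] + v[kix] + stats::rnorm(n, 0, noise_sd)
  sync_estimate <- pmin(pmax(100 * trial$measured_similarity - difference, 0), 100)

  # ---- enjoyment (two-part) ----
  g <- slope_vec(cfg$gamma[setdiff(names(cfg$gamma), "Intercept")])
  d <- slope_vec(cfg$delta[setdiff(names(cfg$delta), "Intercept")])
  ui <- stats::rnorm(J, 0, cfg$tau_inflation)
  ue <- stats::rnorm(J, 0, cfg$tau_enjoy_participant)
  ve <- stats::rnorm(nrow(pool), 0, cfg$tau_enjoy_clip)
  eta <- cfg$gamma$Intercept + as.numeric(zcov %*% g) + ui[jix]
  very_low <- stats::rbinom(n, 1, stats::plogis(eta))
  mu_e <- cfg$delta$Intercept + as.numeric(zcov %*% d) + ue[jix] + ve[kix]
  enjoy_cont <- pmin(pmax(mu_e + stats::rnorm(n, 0, cfg$sigma_enjoy), 11), 100)
  enjoyment <- ifelse(very_low == 1,
                      stats::runif(n, 0, 10.49), # uniform over the low bin
                      enjoy_cont)
  enjoyment <- round(enjoyment)

  # ---- reproducibility: simple similarity-linked rating ----
  reproduce <- pmin(pmax(55 + 8 * z_sim + ue[jix] / 2 +
                           stats::rnorm(n, 0, 15), 0), 100)

  ratings <- rbind(
    data.frame(participant_id = trial$participant_id, clip_id = trial$clip_id,
               question = "sync", value = round(sync_estimate)),
    data.frame(participant_id = trial$participant_id, clip_id = trial$clip_id,
               question = "enjoy", value = enjoyment),
    data.frame(participant_id = trial$participant_id, clip_id = trial$clip_id,
               question = "reproduce", value = round(reproduce))
  )

  accuracy <- data.frame(
    participant_id = trial$participant_id, clip_id = trial$clip_id,
    condition = trial$condition,
    measured_similarity = trial$measured_similarity,
    predictability = trial$predictability,
    difference = difference,
    traits_raw[jix, , drop = FALSE], row.names = NULL)
  enjoyment_tab <- data.frame(
    participant_id = trial$participant_id, clip_id = trial$clip_id,
    condition = trial$condition,
    measured_similarity = trial$measured_similarity,
    predictability = trial$predictability,
    rating = enjoyment,
    traits_raw[jix, , drop = FALSE], row.names = NULL)

  ground_truth <- list(
    alpha_high = cfg$alpha_high, alpha_low = cfg$alpha_low,
    slopes_high = as.list(sh), slopes_low = as.list(sl),
    gamma = c(list(Intercept = cfg$gamma$Intercept), as.list(g)),
    delta = c(list(Intercept = cfg$delta$Intercept), as.list(d)),
    sigma_high = cfg$sigma_high, sigma_low = cfg$sigma_low,
    sigma_enjoy = cfg$sigma_enjoy,
    tau_participant = cfg$tau_participant, tau_clip = cfg$tau_clip,
    tau_inflation = cfg$tau_inflation,
    tau_enjoy_participant = cfg$tau_enjoy_participant,
    tau_enjoy_clip = cfg$tau_enjoy_clip,
    seed = cfg$seed
  )
  list(traits = traits, ratings = ratings, accuracy = accuracy,
       enjoyment = enjoyment_tab, ground_truth = ground_truth)
}
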