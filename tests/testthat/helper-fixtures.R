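# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except what a test itself writes.

# a pose series from a T x 7 x 2 coordinate array (full confidence)
make_series <- function(coords, fps = 60, conf = NULL, person_id = "p") {
  if (is.null(conf)) conf <- matrix(1, dim(coords)[1], 7)
  pose_series(coords, conf, fps = fps, person_id = person_id)
}

# a static plausible 7-joint pose (neck at origin, arms out and down)
base_pose <- function() {
  rbind(
    neck = c(0, 0),
    r_shoulder = c(25, 0), l_shoulder = c(-25, 0),
    r_elbow = c(55, 35), l_elbow = c(-55, 35),
    r_hand = c(75, 70), l_hand = c(-75, 70)
  )
}

# a static dyad recording of T frames from two fixed poses
make_static_dyad <- function(pose_a, pose_b, T_ = 20, fps = 60,
                             condition = "mirroring") {
  expand <- function(p) {
    coords <- array(0, c(T_, 7, 2))
    coords[, , 1] <- matrix(p[, 1], T_, 7, byrow = TRUE)
    coords[, , 2] <- matrix(p[, 2], T_, 7, byrow = TRUE)
    coords
  }
  dyad_recording(make_series(expand(pose_a), fps = fps, person_id = "a"),
                 make_series(expand(pose_b), fps = fps, person_id = "b"),
                 condition = condition)
}

# write OpenPose-style BODY_25 JSON frame files; `people` is a list (one
# element per frame) of lists of 7 x 2 upper-body coordinate matrices
write_openpose_fixture <- function(dir, frames_people, conf = 0.9,
                                   fnames = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  upper_idx <- c(1L, 2L, 5L, 3L, 6L, 4L, 7L) # BODY_25, 0-based
  for (i in seq_along(frames_people)) {
    ppl <- lapply(frames_people[[i]], function(p) {
      flat <- rep(0, 25 * 3)
      for (j in 1:7) {
        k <- upper_idx[j] * 3
        flat[k + 1] <- p[j, 1]; flat[k + 2] <- p[j, 2]; flat[k + 3] <- conf
      }
      list(pose_keypoints_2d = flat)
    })
    fn <- if (is.null(fnames)) sprintf("frame_%06d_keypoints.json", i - 1)
          else fnames[i]
    jsonlite::write_json(list(version = 1.3, people = ppl),
                         file.path(dir, fn), auto_unbox = TRUE, digits = NA)
  }
  dir
}

# independent brute-force sample entropy: plain double loop, no shared code
# with the package implementation
sampen_oracle <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * stats::sd(x)
  A <- 0; B <- 0
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# brute-force 42-entry normalized distance vector, written independently
distvec_oracle <- function(pose) {
  out <- c()
  for (i in 1:7) for (j in 1:7) {
    if (i == j) next
    out <- c(out, sqrt(sum((pose[i, ] - pose[j, ])^2)))
  }
  out / sqrt(sum(out^2))
}

# random valid pose (jittered base pose)
random_pose <- function() base_pose() + matrix(rnorm(14, 0, 10), 7, 2)

# shared small stimulus pool + rater panel, built once per test run
fixture_env <- new.env()
shared_pool <- function() {
  if (is.null(fixture_env$pool))
    fixture_env$pool <- simulate_stimulus_pool(
      n_clips = 24, prop_high = 0.6, n_leaders = 4, seed = 11)$manifest
  fixture_env$pool
}
shared_panel <- function() {
  if (is.null(fixture_env$panel))
    fixture_env$panel <- simulate_raters(
      shared_pool(),
      rater_sim_config(n_raters = 40, n_clips_per_rater = 24, seed = 21))
  fixture_env$panel
}

ALL_TRAITS <- c("extraversion", "self_esteem", "body_perception",
                "body_competence", "empathy", "autistic_traits")

# discrete equal-tailed interval with the same sorted-draw convention as
# hpd_interval, so the width comparison is exact rather than interpolated
et_discrete <- function(x, mass = 0.95) {
  n <- length(x)
  s <- sort(x)
  c(s[max(1L, ceiling((1 - mass) / 2 * n))], s[ceiling((1 + mass) / 2 * n)])
}

# compact model configuration for tests that only need a functioning chain
quick_config <- function(seed = 1, draws = 500, warmup = 300, thin = 1)
  suppressWarnings(model_config(seed = seed, draws = draws, warmup = warmup,
                                thin = thin))
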