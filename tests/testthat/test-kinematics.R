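test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  T_ <- 60
  t <- seq_len(T_)
  for (poly in list(rep(2, T_), 3 + 0.5 * t, 1 + 2 * t - 0.03 * t^2)) {
    coords <- array(poly, c(T_, 7, 2))
    s <- make_series(coords)
    out <- smooth_series(s, window_frames = 13, poly_order = 2)
    expect_lt(max(abs(out$coords - coords)), 1e-9) # endpoints included
  }
})

test_that("smoothing attenuates noise on a sinusoid", {
  withr::local_seed(42)
  T_ <- 600
  t <- (seq_len(T_) - 1) / 60
  clean <- 50 * sin(2 * pi * 0.8 * t)
  noisy <- clean + rnorm(T_, 0, 4)
  coords <- array(rep(noisy, 14), c(T_, 7, 2))
  sm <- smooth_series(make_series(coords))
  expect_lt(var(sm$coords[, 1, 1] - clean), var(noisy - clean))
  expect_true(sm$smoothed)
})

test_that("smooth_series validates its window", {
  s <- make_series(array(0, c(10, 7, 2)))
  expect_error(smooth_series(s, window_frames = 13), "at least 13")
  expect_error(smooth_series(make_series(array(0, c(20, 7, 2))),
                             window_frames = 12), "odd")
})

test_that("pose_distance_vector: 42 entries, unit norm, scale invariance", {
  v <- pose_distance_vector(base_pose())
  expect_length(v$values, 42)
  expect_true(v$valid)
  expect_equal(sqrt(sum(v$values^2)), 1, tolerance = 1e-12)
  # uniform scaling changes nothing after normalization
  v2 <- pose_distance_vector(base_pose() * 2)
  expect_equal(v$values, v2$values, tolerance = 1e-12)
  # degenerate pose: all joints coincident -> invalid zero vector
  v0 <- pose_distance_vector(matrix(5, 7, 2))
  expect_false(v0$valid)
  # low-confidence joint -> invalid
  v3 <- pose_distance_vector(base_pose(), conf = c(1, 1, 1, 0.05, 1, 1, 1))
  expect_false(v3$valid)
})

test_that("frame_similarity matches a brute-force hand computation", {
  # figure A: unit T-pose; figure B: same but hands raised by one arm length
  A <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(2, 0), c(-2, 0), c(3, 0), c(-3, 0))
  B <- A
  B[6, ] <- c(3, -1); B[7, ] <- c(-3, -1)
  va <- distvec_oracle(A); vb <- distvec_oracle(B)
  expected <- sum(va * vb)
  got <- frame_similarity(pose_distance_vector(A), pose_distance_vector(B))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_lt(got, 1)
})

test_that("frame_similarity identity, symmetry, range, isometry invariance", {
  withr::local_seed(7)
  for (i in 1:20) {
    pa <- random_pose(); pb <- random_pose()
    va <- pose_distance_vector(pa); vb <- pose_distance_vector(pb)
    s <- frame_similarity(va, vb)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(frame_similarity(va, va), 1, tolerance = 1e-12)
    expect_equal(s, frame_similarity(vb, va))
    # rigid transform + scaling of one figure leaves similarity unchanged
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    pb2 <- sweep(pb %*% R * runif(1, 0.5, 3), 2, runif(2, -50, 50), `+`)
    pb3 <- pb; pb3[, 1] <- -pb3[, 1] # reflection
    expect_equal(frame_similarity(va, pose_distance_vector(pb2)), s,
                 tolerance = 1e-9)
    expect_equal(frame_similarity(va, pose_distance_vector(pb3)), s,
                 tolerance = 1e-9)
  }
  # invalid input propagates
  bad <- pose_distance_vector(matrix(0, 7, 2))
  expect_true(is.na(frame_similarity(bad, pose_distance_vector(random_pose()))))
})

test_that("ordered 42-pair vector is redundant with unordered 21 pairs", {
  withr::local_seed(8)
  cos21 <- function(pa, pb) {
    d21 <- function(p) {
      idx <- utils::combn(7, 2)
      d <- sqrt(colSums((t(p[idx[1, ], ]) - t(p[idx[2, ], ]))^2))
      d / sqrt(sum(d^2))
    }
    sum(d21(pa) * d21(pb))
  }
  for (i in 1:10) {
    pa <- random_pose(); pb <- random_pose()
    s42 <- frame_similarity(pose_distance_vector(pa), pose_distance_vector(pb))
    expect_equal(s42, cos21(pa, pb), tolerance = 1e-12)
  }
})

test_that("video_similarity: identical figures give mean 1, full coverage", {
  rec <- simulate_dyad(dyad_sim_config("high", follower_lag_ms = 0,
                                       follower_noise_sd = 0, seed = 5))
  rec$series_a <- smooth_series(rec$series_a)
  rec$series_b <- smooth_series(rec$series_b)
  tr <- video_similarity(rec)
  expect_length(tr$per_frame, 600)      # 600 per-frame values per 10-s clip
  expect_equal(tr$mean_similarity, 1, tolerance = 1e-9)
  expect_equal(tr$coverage, 1)
})

test_that("video_similarity warns on unsmoothed input and masks bad frames", {
  rec <- make_static_dyad(base_pose(), base_pose() + 300, T_ = 30)
  expect_warning(video_similarity(rec), "unsmoothed")
  rec$series_a$conf[1:6, 3] <- 0
  tr <- suppressWarnings(video_similarity(rec))
  expect_equal(tr$coverage, 24 / 30)
  expect_true(all(is.na(tr$per_frame[1:6])))
  rec$series_a$conf[] <- 0
  expect_error(suppressWarnings(video_similarity(rec)), "no comparable frames")
})

test_that("an independent random-walk partner scores below self-similarity", {
  n_lower <- 0
  for (s in 1:20) {
    withr::local_seed(s)
    T_ <- 120
    walk <- function() {
      coords <- array(0, c(T_, 7, 2))
      p <- base_pose()
      for (t in seq_len(T_)) {
        p <- p + matrix(rnorm(14, 0, 2), 7, 2)
        coords[t, , ] <- p
      }
      coords
    }
    ca <- walk()
    rec_ind <- dyad_recording(make_series(ca), make_series(walk()))
    rec_self <- dyad_recording(make_series(ca), make_series(ca))
    m_ind <- suppressWarnings(video_similarity(rec_ind))$mean_similarity
    m_self <- suppressWarnings(video_similarity(rec_self))$mean_similarity
    if (m_ind < m_self) n_lower <- n_lower + 1
  }
  expect_equal(n_lower, 20)
})

test_that("sample_entropy equals the brute-force oracle", {
  t <- (0:599) / 60
  x <- sin(2 * pi * 0.5 * t)
  expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 1e-9)
  # frozen regression value computed from the oracle
  expect_equal(sample_entropy(x), 0.13619164, tolerance = 1e-6)
  withr::local_seed(3)
  for (n in c(150, 400)) {
    y <- rnorm(n)
    expect_equal(sample_entropy(y), sampen_oracle(y), tolerance = 1e-9)
    z <- cumsum(rnorm(n))
    expect_equal(sample_entropy(z), sampen_oracle(z), tolerance = 1e-9)
  }
})

test_that("sample_entropy edge conventions", {
  expect_equal(sample_entropy(rep(3, 50)), 0) # all templates match at r = 0
  expect_error(sample_entropy(1:3), "too short")
  # no matches at all -> undefined, flagged
  expect_warning(res <- sample_entropy(c(0, 1e6, -1e6, 2e6, -2e6, 3e6)),
                 "undefined")
  expect_true(is.nan(res))
})

test_that("iid noise has higher sample entropy than a same-variance sinusoid", {
  t <- (0:599) / 60
  sine <- sin(2 * pi * 0.5 * t)
  wins <- 0
  for (s in 1:20) {
    withr::local_seed(100 + s)
    noise <- rnorm(600, 0, sd(sine))
    if (sample_entropy(noise) > sample_entropy(sine)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("video_predictability returns 8 channels averaged per clip", {
  rec <- simulate_dyad(dyad_sim_config("high", seed = 12))
  rec$series_a <- smooth_series(rec$series_a)
  rec$series_b <- smooth_series(rec$series_b)
  panel <- video_predictability(rec)
  expect_length(panel$channel_values, 8)
  expect_true(all(is.finite(panel$channel_values)))
  expect_equal(panel$predictability, mean(panel$channel_values))
  expect_length(panel$excluded_channels, 0)
})

test_that("constant wrists yield zero entropy; masked person is excluded", {
  rec <- simulate_dyad(dyad_sim_config("high", seed = 13))
  # freeze person b's wrists: perfectly constant -> entropy 0, included
  for (j in 6:7) for (d in 1:2) rec$series_b$coords[, j, d] <- 100
  panel <- video_predictability(rec)
  bchan <- grepl("^b\\.", names(panel$channel_values))
  expect_true(all(panel$channel_values[bchan] == 0))
  expect_equal(panel$predictability, mean(panel$channel_values))

  # all-invalid wrists for person b -> 4 channels excluded with a warning
  rec2 <- simulate_dyad(dyad_sim_config("high", seed = 13))
  rec2$series_b$conf[, 6:7] <- 0
  expect_warning(panel2 <- video_predictability(rec2), "excluding")
  expect_length(panel2$excluded_channels, 4)
  expect_equal(panel2$predictability,
               mean(panel2$channel_values[!grepl("^b\\.", names(panel2$channel_values))]))
})
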