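#' Savitzky-Golay smoothing of a pose series
#'
#' Smooths each coordinate channel (joint x axis) independently with a
#' Savitzky-Golay filter: a least-squares polynomial of order `poly_order`
#' is fit within a sliding window and evaluated at the window centre. At the
#' series ends, where the full window does not fit, the window is truncated
#' to the available samples and the polynomial is evaluated at the off-centre
#' position; an order-`poly_order` filter therefore reproduces any polynomial
#' trajectory of that degree exactly, endpoints included. Confidences pass
#' through unchanged.
#'
#' @param series a [pose_series()].
#' @param window_frames odd window length in frames (default 13).
#' @param poly_order polynomial order (default 2), `< window_frames`.
#' @return A smoothed `pose_series` (flagged `smoothed = TRUE`).
#' @export
smooth_series <- function(series, window_frames = 13, poly_order = 2) {
  stopifnot(inherits(series, "pose_series"))
  if (window_frames %% 2 != 1) stop_dyadsync("window_frames must be odd")
  if (window_frames <= poly_order)
    stop_dyadsync("window_frames must exceed poly_order")
  T_ <- n_frames(series)
  if (T_ < window_frames)
    stop_dyadsync("series too short: need at least ", window_frames,
                  " frames for a window of ", window_frames)
  out <- series
  for (j in 1:7) for (d in 1:2)
    out$coords[, j, d] <- savgol_smooth(series$coords[, j, d],
                                        window_frames, poly_order)
  out$smoothed <- TRUE
  out
}

# Savitzky-Golay on a single numeric vector. Interior points use the
# central-window convolution; each end point gets its own truncated-window
# least-squares fit evaluated at its position.
savgol_smooth <- function(x, window, order) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  # interior convolution coefficients: first row of the hat matrix at centre
  A <- outer(-h:h, 0:order, `^`)
  # coefficients c s.t. smoothed centre = c %*% window values
  cc <- (solve(crossprod(A), t(A)))[1, ]
  y <- stats::filter(x, rev(cc), sides = 2)
  y <- as.numeric(y)
  fit_at <- function(idx, at) {
    B <- outer(idx - at, 0:order, `^`)
    (solve(crossprod(B), crossprod(B, x[idx])))[1, 1]
  }
  for (t in seq_len(h)) y[t] <- fit_at(1:(t + h), t)
  for (t in (n - h + 1L):n) y[t] <- fit_at((t - h):n, t)
  y
}

# index pairs for the 42 ordered joint pairs, row-major over (i, j), i != j
POSE_PAIRS <- {
  g <- expand.grid(j = 1:7, i = 1:7)[, 2:1]
  g <- g[g$i != g$j, ]
  as.matrix(g)
}

#' Pose-distance vector for one figure in one frame
#'
#' Computes the Euclidean distances between every ordered pair of the seven
#' tracked joints (7 x 6 = 42 entries; the "pose matrix" flattened in a
#' fixed, documented order: pairs (i, j), i != j, enumerated row-major) and
#' L2-normalizes the vector. Normalization makes the representation
#' body-centric: invariant to the figure's position, overall size, and any
#' rigid motion of the camera frame.
#'
#' The vector is flagged invalid when any joint's confidence falls below
#' `conf_threshold`, or when all joints coincide (zero norm).
#'
#' @param frame_joints `7 x 2` matrix of joint coordinates (canonical order).
#' @param conf numeric vector of 7 confidences (default all 1).
#' @param conf_threshold minimum per-joint confidence (default 0.1).
#' @return A list with `values` (length-42 numeric, unit L2 norm when valid)
#'   and `valid` (logical), of class `pose_distance_vector`.
#' @export
pose_distance_vector <- function(frame_joints, conf = rep(1, 7),
                                 conf_threshold = 0.1) {
  frame_joints <- as.matrix(frame_joints)
  if (!all(dim(frame_joints) == c(7, 2)))
    stop_dyadsync("frame_joints must be a 7 x 2 matrix")
  d <- sqrt((frame_joints[POSE_PAIRS[, 1], 1] - frame_joints[POSE_PAIRS[, 2], 1])^2 +
            (frame_joints[POSE_PAIRS[, 1], 2] - frame_joints[POSE_PAIRS[, 2], 2])^2)
  nrm <- sqrt(sum(d^2))
  valid <- all(conf >= conf_threshold) && nrm > 0 && all(is.finite(d))
  values <- if (valid) d / nrm else d * 0
  structure(list(values = values, valid = valid),
            class = "pose_distance_vector")
}

#' Frame-wise similarity of two pose-distance vectors
#'
#' Cosine similarity of the two normalized, nonnegative distance vectors.
#' Because both vectors are elementwise nonnegative with unit norm, the
#' value lies in `[0, 1]`: 0 means no similarity, 1 means the two poses have
#' proportional (after normalization, identical) pairwise joint distances.
#'
#' @param vec_a,vec_b objects from [pose_distance_vector()].
#' @return Similarity in `[0, 1]`, or `NA` if either vector is invalid.
#' @export
frame_similarity <- function(vec_a, vec_b) {
  if (!isTRUE(vec_a$valid) || !isTRUE(vec_b$valid)) return(NA_real_)
  s <- sum(vec_a$values * vec_b$values)
  min(max(s, 0), 1)
}

#' Per-frame and mean similarity for a dyad recording
#'
#' Computes the pose-distance-vector similarity between the two figures for
#' every frame, and the mean over valid frames (frames where both figures
#' have all joints at or above the confidence threshold). The `coverage`
#' field reports the fraction of frames that entered the mean.
#'
#' Similarity is intended to be measured on smoothed series; a warning is
#' issued when the input has no smoothing flag.
#'
#' @param rec a [dyad_recording()].
#' @param conf_threshold per-joint confidence threshold (default 0.1).
#' @return A list of class `similarity_trace` with `per_frame` (length-T
#'   numeric, `NA` at invalid frames), `mean_similarity`, and `coverage`.
#' @export
video_similarity <- function(rec, conf_threshold = 0.1) {
  stopifnot(inherits(rec, "dyad_recording"))
  if (!isTRUE(rec$series_a$smoothed) || !isTRUE(rec$series_b$smoothed))
    warning("computing similarity on unsmoothed series; see smooth_series()")
  T_ <- n_frames(rec)
  va <- distance_vectors(rec$series_a, conf_threshold)
  vb <- distance_vectors(rec$series_b, conf_threshold)
  per_frame <- rowSums(va$values * vb$values)
  per_frame <- pmin(pmax(per_frame, 0), 1)
  ok <- va$valid & vb$valid
  per_frame[!ok] <- NA_real_
  if (!any(ok)) stop_dyadsync("no comparable frames: every frame invalid")
  structure(
    list(per_frame = per_frame,
         mean_similarity = mean(per_frame[ok]),
         coverage = mean(ok)),
    class = "similarity_trace"
  )
}

# vectorized pose_distance_vector over all frames of a series:
# returns T x 42 matrix of normalized distances plus validity vector
distance_vectors <- function(series, conf_threshold = 0.1) {
  x <- series$coords[, , 1, drop = FALSE][, , 1]
  y <- series$coords[, , 2, drop = FALSE][, , 1]
  if (is.null(dim(x))) { x <- matrix(x, 1); y <- matrix(y, 1) }
  d <- sqrt((x[, POSE_PAIRS[, 1], drop = FALSE] - x[, POSE_PAIRS[, 2], drop = FALSE])^2 +
            (y[, POSE_PAIRS[, 1], drop = FALSE] - y[, POSE_PAIRS[, 2], drop = FALSE])^2)
  nrm <- sqrt(rowSums(d^2))
  valid <- apply(series$conf >= conf_threshold, 1, all) & nrm > 0 &
    apply(is.finite(d), 1, all)
  d <- d / ifelse(nrm > 0, nrm, 1)
  d[!valid, ] <- 0
  list(values = d, valid = valid)
}

#' Sample entropy of a univariate series
#'
#' SampEn(m, r): the negative natural log of the conditional probability
#' that two subsequences matching for `m` points (Chebyshev distance at most
#' `r`) also match for `m + 1` points. Template pairs exclude self-matches;
#' the tolerance is `r_factor` times the sample standard deviation of `x`.
#' Values near 0 indicate a regular, predictable signal; larger values a
#' more irregular one.
#'
#' Returns `NaN` (with a warning) when no template pairs match at length `m`
#' or `m + 1`, in which case the statistic is undefined.
#'
#' @param x numeric vector, length at least `m + 2`.
#' @param m template length (default 2).
#' @param r_factor tolerance as a multiple of `sd(x)` (default 0.2).
#' @return Nonnegative scalar, or `NaN` when undefined.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  if (n < m + 2) stop_dyadsync("series too short: need length >= m + 2")
  if (any(!is.finite(x))) stop_dyadsync("series contains non-finite values")
  r <- r_factor * stats::sd(x)
  # templates of length m and m+1, both drawn from the first n - m start
  # positions so the conditional probability is over the same pair set
  count_pairs <- function(len) {
    emb <- stats::embed(x, len)[seq_len(n - m), rev(seq_len(len)), drop = FALSE]
    dm <- as.matrix(stats::dist(emb, method = "maximum"))
    (sum(dm <= r) - nrow(emb)) / 2
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (A == 0 || B == 0) {
    warning("sample entropy undefined: no matching template pairs")
    return(NaN)
  }
  -log(A / B)
}

#' Wrist-movement predictability panel for a dyad recording
#'
#' Computes the sample entropy of the x and y coordinate series of each
#' person's left and right wrist (up to 2 coordinates x 2 wrists x 2 people
#' = 8 channels) and averages the defined channels into a single
#' `predictability` value per clip (lower = more regular, more predictable
#' movement).
#'
#' Channels whose wrist keypoints are unreliable (mean confidence below
#' `conf_threshold`) or whose entropy is undefined are excluded from the
#' mean and listed in `excluded_channels`, with a warning.
#'
#' @param rec a [dyad_recording()] (ideally smoothed).
#' @param m,r_factor passed to [sample_entropy()].
#' @param conf_threshold minimum mean wrist confidence per channel.
#' @return A list of class `entropy_panel` with `channel_values` (named
#'   length-8 numeric, `NA` where excluded), `excluded_channels`, and
#'   `predictability`.
#' @export
video_predictability <- function(rec, m = 2, r_factor = 0.2,
                                 conf_threshold = 0.1) {
  stopifnot(inherits(rec, "dyad_recording"))
  wrists <- c(r_hand = 6L, l_hand = 7L)
  vals <- stats::setNames(rep(NA_real_, 8), apply(
    expand.grid(c("x", "y"), names(wrists), c("a", "b")), 1,
    function(r) paste(r[3], r[2], r[1], sep = ".")))
  for (person in c("a", "b")) {
    s <- rec[[paste0("series_", person)]]
    for (w in names(wrists)) {
      j <- wrists[[w]]
      reliable <- mean(s$conf[, j]) >= conf_threshold
      for (d in 1:2) {
        ch <- paste(person, w, c("x", "y")[d], sep = ".")
        if (!reliable) next
        vals[ch] <- suppressWarnings(
          tryCatch(sample_entropy(s$coords[, j, d], m = m, r_factor = r_factor),
                   error = function(e) NaN))
      }
    }
  }
  defined <- is.finite(vals)
  excluded <- names(vals)[!defined]
  if (!any(defined))
    stop_dyadsync("all 8 wrist channels undefined; cannot compute predictability")
  if (length(excluded) > 0)
    warning("excluding undefined entropy channel(s): ",
            paste(excluded, collapse = ", "))
  vals[!defined] <- NA_real_
  structure(
    list(channel_values = vals, excluded_channels = excluded,
         predictability = mean(vals[defined])),
    class = "entropy_panel"
  )
}

#' Kinematic summary for one clip
#'
#' Convenience wrapper: smooths both series, then computes measured
#' similarity ([video_similarity()]) and predictability
#' ([video_predictability()]) — the two objective covariates used by the
#' rating models.
#'
#' @param rec a [dyad_recording()] of one clip.
#' @param clip_id label for the clip.
#' @param smooth whether to Savitzky-Golay smooth first (default TRUE).
#' @return A one-row data frame: `clip_id`, `measured_similarity`,
#'   `predictability`, `coverage`.
#' @export
kinematic_summary <- function(rec, clip_id = rec$dyad_id, smooth = TRUE) {
  if (smooth) {
    rec$series_a <- smooth_series(rec$series_a)
    rec$series_b <- smooth_series(rec$series_b)
  }
  sim <- video_similarity(rec)
  ent <- suppressWarnings(video_predictability(rec))
  data.frame(clip_id = clip_id,
             measured_similarity = sim$mean_similarity,
             predictability = ent$predictability,
             coverage = sim$coverage,
             stringsAsFactors = FALSE)
}
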