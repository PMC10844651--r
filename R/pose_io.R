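#' Read per-frame OpenPose JSON keypoint files
#'
#' Reads a directory of OpenPose output files (one JSON file per video frame,
#' BODY_25 keypoint layout) and extracts, for each detected person, the seven
#' upper-body joints used by this package (see [dyad_joints()]). Files are
#' processed in filename-sorted order so the frame index is well defined
#' regardless of filesystem enumeration order.
#'
#' A frame in which only one person was detected is completed with a second,
#' all-zero-confidence person so that every frame carries exactly two people;
#' downstream code treats zero confidence as "missing".
#'
#' @param dir directory containing `*.json` frame files.
#' @return A list with one element per frame; each element is a list of two
#'   `7 x 3` matrices (columns x, y, confidence; rows in canonical joint
#'   order).
#' @export
read_openpose_frames <- function(dir) {
  if (!dir.exists(dir)) stop_dyadsync("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0) stop_dyadsync("no frames: no .json files in ", dir)
  lapply(files, read_openpose_frame)
}

read_openpose_frame <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) stop_dyadsync("malformed JSON in ", basename(path), ": ",
                                      conditionMessage(e))
  )
  kp <- obj$people$pose_keypoints_2d
  if (is.null(kp)) kp <- list()
  if (is.matrix(kp)) kp <- asplit(kp, 1) # simplified to a matrix when equal-length
  if (!is.list(kp)) kp <- list(kp)
  n_people <- length(kp)
  if (n_people > 2)
    stop_dyadsync("frame ", basename(path), " contains ", n_people,
                  " people; only dyads (<= 2) are supported")
  people <- lapply(kp, function(flat) {
    flat <- as.numeric(flat)
    if (length(flat) %% 3 != 0 || length(flat) < 3 * 25)
      stop_dyadsync("malformed keypoint vector in ", basename(path),
                    " (expected flat x,y,confidence triplets, BODY_25)")
    m <- matrix(flat, ncol = 3, byrow = TRUE)
    out <- m[BODY25_UPPER_IDX + 1L, , drop = FALSE]
    dimnames(out) <- list(DYADSYNC_JOINTS, c("x", "y", "confidence"))
    out
  })
  while (length(people) < 2) {
    empty <- matrix(0, nrow = 7, ncol = 3,
                    dimnames = list(DYADSYNC_JOINTS, c("x", "y", "confidence")))
    people <- c(people, list(empty))
  }
  people
}

#' Assemble a dyad recording from per-frame keypoint sets
#'
#' Tracks the two people across frames by horizontal position: the person
#' whose detected keypoints have the smaller mean x becomes `series_a` (the
#' left-hand figure). The stimuli keep each figure on its own side of the
#' frame, so no re-identification beyond this ordering is attempted. Frames
#' where one person is missing (all confidences zero) keep the present person
#' on the side closer to its running mean position.
#'
#' @param frames list as produced by [read_openpose_frames()].
#' @param fps frames per second of the source video (default 60).
#' @param dyad_id,leader_id,condition metadata passed to [dyad_recording()].
#' @return A [dyad_recording()].
#' @export
assemble_dyad <- function(frames, fps = 60, dyad_id = "dyad",
                          leader_id = "leader", condition = "mirroring") {
  if (length(frames) < 1) stop_dyadsync("need at least one frame")
  T_ <- length(frames)
  coords <- array(0, dim = c(T_, 7, 2, 2)) # frame, joint, xy, person-slot
  conf <- array(0, dim = c(T_, 7, 2))
  mean_x <- function(p) {
    det <- p[, "confidence"] > 0
    if (!any(det)) NA_real_ else mean(p[det, "x"])
  }
  run_mx <- c(NA_real_, NA_real_) # running mean x per slot (a = left, b = right)
  for (t in seq_len(T_)) {
    ppl <- frames[[t]]
    if (!is.list(ppl) || length(ppl) != 2)
      stop_dyadsync("frame ", t, ": expected exactly two person entries")
    mx <- vapply(ppl, mean_x, numeric(1))
    present <- !is.na(mx)
    if (sum(present) == 2) {
      ord <- order(mx)
    } else if (sum(present) == 1) {
      i <- which(present)
      slot <- if (all(is.na(run_mx))) 1L
              else which.min(abs(run_mx - mx[i]))
      ord <- if (slot == 1L) c(i, setdiff(1:2, i)) else c(setdiff(1:2, i), i)
    } else {
      ord <- 1:2
    }
    for (s in 1:2) {
      p <- ppl[[ord[s]]]
      coords[t, , , s] <- p[, c("x", "y")]
      conf[t, , s] <- p[, "confidence"]
      m <- mean_x(p)
      if (!is.na(m)) run_mx[s] <- if (is.na(run_mx[s])) m else 0.9 * run_mx[s] + 0.1 * m
    }
  }
  grab <- function(slot, label) {
    co <- coords[, , , slot, drop = FALSE]
    dim(co) <- c(T_, 7L, 2L)
    pose_series(co, matrix(conf[, , slot], T_, 7), fps = fps,
                person_id = label)
  }
  dyad_recording(grab(1, "a"), grab(2, "b"),
                 dyad_id = dyad_id, leader_id = leader_id,
                 condition = condition)
}

#' Interpolate short tracking gaps in a pose series
#'
#' Runs of confidence-0 samples (per joint) of length at most `max_gap_frames`
#' that are bracketed by detected samples are filled by linear interpolation
#' of each coordinate; filled samples are flagged with confidence 0.5 so they
#' remain distinguishable from raw detections. Longer runs, and runs touching
#' either end of the series, are left untouched.
#'
#' @param series a [pose_series()].
#' @param max_gap_frames maximum gap length to fill (frames, >= 0).
#' @return A new `pose_series` with qualifying gaps filled.
#' @export
interpolate_gaps <- function(series, max_gap_frames = 5) {
  stopifnot(inherits(series, "pose_series"))
  if (max_gap_frames < 0) stop_dyadsync("max_gap_frames must be >= 0")
  if (max_gap_frames == 0) return(series)
  out <- series
  T_ <- n_frames(series)
  for (j in 1:7) {
    miss <- series$conf[, j] == 0
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      s <- starts[g]; e <- ends[g]
      if (s == 1L || e == T_) next            # no anchor on one side
      if (r$lengths[g] > max_gap_frames) next
      for (d in 1:2) {
        v0 <- series$coords[s - 1L, j, d]
        v1 <- series$coords[e + 1L, j, d]
        w <- seq_len(e - s + 1L) / (e - s + 2L)
        out$coords[s:e, j, d] <- v0 + w * (v1 - v0)
      }
      out$conf[s:e, j] <- 0.5
    }
  }
  out
}

CSV_COLS <- c("frame", "person", "joint", "x", "y", "confidence")

#' Write a dyad recording to long-format CSV
#'
#' Persists a [dyad_recording()] as UTF-8 CSV with columns
#' `frame, person, joint, x, y, confidence` (one row per frame x person x
#' joint; "." decimal separator). Recording metadata (dyad id, leader id,
#' condition, fps) is stored in `#`-prefixed comment lines before the header
#' and restored by [read_timeseries_csv()].
#'
#' @param rec a [dyad_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(rec, path) {
  stopifnot(inherits(rec, "dyad_recording"))
  T_ <- n_frames(rec)
  one <- function(s, label) {
    data.frame(
      frame = rep(seq_len(T_), each = 7),
      person = label,
      joint = rep(DYADSYNC_JOINTS, times = T_),
      x = as.vector(t(s$coords[, , 1, drop = FALSE][, , 1])),
      y = as.vector(t(s$coords[, , 2, drop = FALSE][, , 1])),
      confidence = as.vector(t(s$conf))
    )
  }
  df <- rbind(one(rec$series_a, "a"), one(rec$series_b, "b"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# dyadsync dyad_id=%s leader_id=%s condition=%s fps=%.10g",
                     rec$dyad_id, rec$leader_id, rec$condition,
                     rec$series_a$fps), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dyad recording from long-format CSV
#'
#' Inverse of [write_timeseries_csv()]. Rows may appear in any order; joints
#' are reordered into the canonical order of [dyad_joints()] on read.
#' Coordinates round-trip to better than 1e-9.
#'
#' @param path CSV file path.
#' @return A [dyad_recording()].
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop_dyadsync("file not found: ", path)
  first <- readLines(path, n = 1)
  meta <- list(dyad_id = "dyad", leader_id = "leader",
               condition = "mirroring", fps = 60)
  if (startsWith(first, "# dyadsync")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- if (p[1] == "fps") as.numeric(p[2]) else p[2]
    }
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(CSV_COLS, names(df))
  if (length(missing) > 0)
    stop_dyadsync("CSV schema error: missing column(s) ",
                  paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$joint), DYADSYNC_JOINTS)
  if (length(bad) > 0)
    stop_dyadsync("unknown joint name(s): ", paste(bad, collapse = ", "))
  frames <- sort(unique(df$frame))
  T_ <- length(frames)
  build <- function(label) {
    sub <- df[df$person == label, , drop = FALSE]
    if (nrow(sub) != T_ * 7)
      stop_dyadsync("person '", label, "' does not have 7 joints in every frame")
    fi <- match(sub$frame, frames)
    ji <- match(sub$joint, DYADSYNC_JOINTS)
    coords <- array(NA_real_, c(T_, 7, 2))
    conf <- matrix(NA_real_, T_, 7)
    coords[cbind(fi, ji, 1L)] <- sub$x
    coords[cbind(fi, ji, 2L)] <- sub$y
    conf[cbind(fi, ji)] <- sub$confidence
    pose_series(coords, conf, fps = meta$fps, person_id = label)
  }
  dyad_recording(build("a"), build("b"), dyad_id = meta$dyad_id,
                 leader_id = meta$leader_id, condition = meta$condition)
}
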