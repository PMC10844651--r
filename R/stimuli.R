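#' Segment a recording into fixed-length clips
#'
#' Cuts a dyad recording into consecutive, non-overlapping clips of
#' `clip_seconds` (default 10 s; 600 frames at 60 fps). A trailing remainder
#' shorter than one clip is dropped. Each clip inherits the source
#' recording's metadata; clip ids append a segment counter.
#'
#' @param rec a [dyad_recording()].
#' @param clip_seconds clip length in seconds (default 10).
#' @return List of `dyad_recording` clips.
#' @export
segment_clips <- function(rec, clip_seconds = 10) {
  stopifnot(inherits(rec, "dyad_recording"))
  fps <- rec$series_a$fps
  L <- as.integer(round(clip_seconds * fps))
  T_ <- n_frames(rec)
  if (T_ < L)
    stop_dyadsync("recording too short: ", T_, " frames < one clip of ", L)
  n <- T_ %/% L
  lapply(seq_len(n), function(i) {
    idx <- ((i - 1L) * L + 1L):(i * L)
    slice <- function(s) {
      out <- pose_series(s$coords[idx, , , drop = FALSE],
                         s$conf[idx, , drop = FALSE],
                         fps = s$fps, person_id = s$person_id)
      out$smoothed <- s$smoothed
      out
    }
    dyad_recording(slice(rec$series_a), slice(rec$series_b),
                   dyad_id = sprintf("%s_seg%02d", rec$dyad_id, i),
                   leader_id = rec$leader_id, condition = rec$condition)
  })
}

CB_CELLS <- expand.grid(leader_color = c("red", "blue"),
                        leader_side = c("left", "right"),
                        stringsAsFactors = FALSE)

#' Counterbalance leader colour and side across clips
#'
#' Assigns each clip a leader colour (red/blue) and side (left/right) such
#' that the four colour-by-side cells are as equal as possible overall
#' (counts differ by at most 1) and within each leader's clips where the
#' count divides evenly. Full cycles through the four cells are dealt within
#' each leader; per-leader remainders then go to the globally least-used
#' cell, breaking ties toward balancing the colour and side margins.
#' Deterministic given the seed.
#'
#' @param clips data frame with at least `clip_id` and `leader_id` columns.
#' @param seed integer RNG seed.
#' @return `clips` with `leader_color` and `leader_side` columns added.
#' @export
counterbalance_assign <- function(clips, seed = 1) {
  stopifnot(is.data.frame(clips), all(c("clip_id", "leader_id") %in% names(clips)))
  if (nrow(clips) < 1) stop_dyadsync("need at least one clip")
  withr::local_seed(seed)
  cell <- integer(nrow(clips))
  counts <- rep(0L, 4)
  color_of <- c(1L, 2L, 1L, 2L) # cell -> color index (red=1, blue=2)
  side_of <- c(1L, 1L, 2L, 2L)  # cell -> side index (left=1, right=2)
  col_counts <- c(0L, 0L); side_counts <- c(0L, 0L)
  remainders <- integer(0)
  for (ld in unique(clips$leader_id)) {
    idx <- which(clips$leader_id == ld)
    idx <- idx[sample.int(length(idx))]
    n_full <- (length(idx) %/% 4L) * 4L
    if (n_full > 0) {
      cyc <- rep(sample(4L), length.out = n_full)
      cell[idx[seq_len(n_full)]] <- cyc
    }
    if (length(idx) > n_full) remainders <- c(remainders, idx[(n_full + 1L):length(idx)])
  }
  counts <- tabulate(cell[cell > 0L], 4L)
  col_counts <- c(sum(counts[color_of == 1L]), sum(counts[color_of == 2L]))
  side_counts <- c(sum(counts[side_of == 1L]), sum(counts[side_of == 2L]))
  for (i in remainders) {
    score <- counts * 100 + col_counts[color_of] * 10 + side_counts[side_of] +
      stats::runif(4) * 0.5 # random tie-break, deterministic under seed
    k <- which.min(score)
    cell[i] <- k
    counts[k] <- counts[k] + 1L
    col_counts[color_of[k]] <- col_counts[color_of[k]] + 1L
    side_counts[side_of[k]] <- side_counts[side_of[k]] + 1L
  }
  clips$leader_color <- CB_CELLS$leader_color[cell]
  clips$leader_side <- CB_CELLS$leader_side[cell]
  clips
}

#' Split a counterbalanced clip pool into two overlapping subsets
#'
#' Splits a pool of `2 * (subset_size - overlap) + overlap` clips (198 at
#' the defaults) into subsets A and B of `subset_size` clips that share
#' exactly `overlap` clips. Per leader, the unique (non-shared) clips are
#' split as evenly as possible (difference at most 1), and each
#' colour-by-side counterbalancing cell is kept within 1 clip of even
#' between the subsets.
#'
#' Groups of clips sharing a (leader, cell) pair are dealt alternately to A
#' and B; the odd leftovers — one per odd-sized group — are oriented by an
#' Eulerian-trail walk on the leader/cell incidence multigraph, which
#' guarantees every leader margin and cell margin stays within 1 while the
#' two subsets stay the same size.
#'
#' @param clips data frame with `clip_id`, `leader_id`, `leader_color`,
#'   `leader_side` (see [counterbalance_assign()]).
#' @param overlap number of clips shared by both subsets (default 2).
#' @param subset_size clips per subset (default 100).
#' @param seed integer RNG seed.
#' @return `clips` with a `subset` column: `"A"`, `"B"`, or `"both"`.
#' @export
split_subsets <- function(clips, overlap = 2, subset_size = 100, seed = 1) {
  need <- 2L * (subset_size - overlap) + overlap
  if (nrow(clips) != need)
    stop_dyadsync("pool size ", nrow(clips), " incompatible: need exactly ",
                  need, " clips for subset_size=", subset_size,
                  ", overlap=", overlap)
  stopifnot(all(c("leader_id", "leader_color", "leader_side") %in% names(clips)))
  withr::local_seed(seed)
  clips$subset <- NA_character_
  shared <- sample(nrow(clips), overlap)
  clips$subset[shared] <- "both"
  cellkey <- paste(clips$leader_color, clips$leader_side)
  grp <- interaction(clips$leader_id, cellkey, drop = TRUE)
  pend_i <- integer(0); pend_leader <- character(0); pend_cell <- character(0)
  for (g in levels(grp)) {
    idx <- which(grp == g & is.na(clips$subset))
    if (length(idx) == 0) next
    idx <- idx[sample.int(length(idx))]
    n_even <- (length(idx) %/% 2L) * 2L
    if (n_even > 0)
      clips$subset[idx[seq_len(n_even)]] <- rep(sample(c("A", "B")),
                                                length.out = n_even)
    if (length(idx) > n_even) {
      i <- idx[length(idx)]
      pend_i <- c(pend_i, i)
      pend_leader <- c(pend_leader, clips$leader_id[i])
      pend_cell <- c(pend_cell, cellkey[i])
    }
  }
  if (length(pend_i) > 0)
    clips$subset[pend_i] <- orient_pendings(pend_leader, pend_cell)
  clips
}

# Orient leftover clips (edges of the bipartite leader/cell multigraph) to
# sides A/B so every node's A-minus-B imbalance is at most 1 and the overall
# split is as even as the edge count allows. Eulerian trails are walked with
# alternating labels; odd-length trails alternate their starting label so
# their surpluses cancel pairwise.
orient_pendings <- function(leaders, cells) {
  m <- length(leaders)
  lnode <- paste0("L:", leaders)
  cnode <- paste0("C:", cells)
  nodes <- unique(c(lnode, cnode))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) integer(0))
  for (e in seq_len(m)) {
    adj[[lnode[e]]] <- c(adj[[lnode[e]]], e)
    adj[[cnode[e]]] <- c(adj[[cnode[e]]], e)
  }
  used <- rep(FALSE, m)
  other_end <- function(e, v) if (lnode[e] == v) cnode[e] else lnode[e]
  walk_trail <- function(start) {
    v <- start; trail <- integer(0)
    repeat {
      es <- adj[[v]]; es <- es[!used[es]]
      if (length(es) == 0) break
      e <- es[1]
      used[e] <<- TRUE
      trail <- c(trail, e)
      v <- other_end(e, v)
    }
    trail
  }
  deg_unused <- function(v) sum(!used[adj[[v]]])
  labels <- character(m)
  odd_start <- "A" # alternate so odd-length trails cancel
  repeat {
    odd_nodes <- nodes[vapply(nodes, deg_unused, 0L) %% 2L == 1L]
    any_nodes <- nodes[vapply(nodes, deg_unused, 0L) > 0L]
    if (length(any_nodes) == 0) break
    start <- if (length(odd_nodes) > 0) odd_nodes[1] else any_nodes[1]
    trail <- walk_trail(start)
    first <- if (length(trail) %% 2L == 1L) {
      s <- odd_start; odd_start <- if (odd_start == "A") "B" else "A"; s
    } else "A"
    labs <- rep(c(first, setdiff(c("A", "B"), first)), length.out = length(trail))
    labels[trail] <- labs
  }
  labels
}

QUESTIONS <- c("sync", "enjoy", "reproduce")

#' Build one participant's trial schedule
#'
#' Samples `n_videos` clips (default 50) without replacement from a stimulus
#' subset, creates one trial per clip per rating question (synchrony,
#' enjoyment, reproducibility) in fully randomized order, and inserts 3
#' standalone attention-check trials at uniformly random, mutually
#' non-adjacent positions — 153 trials in total at the defaults.
#'
#' @param subset data frame of available clips (needs `clip_id`).
#' @param participant_id label for the participant.
#' @param n_videos clips sampled per participant (default 50).
#' @param seed integer RNG seed.
#' @return A data frame of class `trial_schedule`: `participant_id`,
#'   `position`, `clip_id` (`NA` for attention trials), `question`.
#' @export
build_trial_schedule <- function(subset, participant_id = "P001",
                                 n_videos = 50, seed = 1) {
  stopifnot(is.data.frame(subset), "clip_id" %in% names(subset))
  if (nrow(subset) < n_videos)
    stop_dyadsync("subset has ", nrow(subset), " clips; need at least ", n_videos)
  withr::local_seed(seed)
  clip_ids <- subset$clip_id[sample.int(nrow(subset), n_videos)]
  trials <- expand.grid(clip_id = clip_ids, question = QUESTIONS,
                        stringsAsFactors = FALSE)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  n_total <- nrow(trials) + 3L
  repeat {
    att_pos <- sort(sample(n_total, 3))
    if (all(diff(att_pos) > 1)) break
  }
  sched <- data.frame(participant_id = participant_id,
                      position = seq_len(n_total),
                      clip_id = NA_character_,
                      question = NA_character_,
                      stringsAsFactors = FALSE)
  sched$question[att_pos] <- "attention"
  real <- setdiff(seq_len(n_total), att_pos)
  sched$clip_id[real] <- as.character(trials$clip_id)
  sched$question[real] <- trials$question
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Score attention-check responses and apply the inclusion rule
#'
#' The attention question asks how much the stick figures resembled
#' automobiles; the correct answer is "not at all" (0), and slider responses
#' in `[0, 25]` count as correct. Participants are included when at least
#' 2 of 3 checks are correct.
#'
#' @param responses numeric vector of exactly 3 slider values in `[0, 100]`.
#' @param participant_id label.
#' @return A list of class `attention_result`: `participant_id`, `responses`,
#'   `n_correct`, `included`.
#' @export
score_attention <- function(responses, participant_id = "P001") {
  if (length(responses) != 3)
    stop_dyadsync("expected exactly 3 attention responses")
  if (any(!is.finite(responses)) || any(responses < 0 | responses > 100))
    stop_dyadsync("attention responses must lie in [0, 100]")
  n_correct <- sum(responses <= 25)
  structure(
    list(participant_id = participant_id, responses = responses,
         n_correct = n_correct, included = n_correct >= 2),
    class = "attention_result"
  )
}
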