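make_pool_df <- function(n, n_leaders = 4) {
  data.frame(clip_id = sprintf("c%03d", seq_len(n)),
             leader_id = sprintf("L%02d", rep(seq_len(n_leaders),
                                              length.out = n)),
             stringsAsFactors = FALSE)
}

test_that("segment_clips cuts exact non-overlapping segments", {
  long <- make_static_dyad(base_pose(), base_pose() + 300, T_ = 65 * 60)
  clips <- segment_clips(long)
  expect_length(clips, 6)
  expect_true(all(vapply(clips, n_frames, 1L) == 600))
  expect_equal(segment_clips(make_static_dyad(base_pose(), base_pose() + 1,
                                              T_ = 600)) |> length(), 1)
  # 2412 frames -> 4 clips, 12-frame remainder dropped
  clips4 <- segment_clips(make_static_dyad(base_pose(), base_pose() + 1,
                                           T_ = 2412))
  expect_length(clips4, 4)
  expect_error(segment_clips(make_static_dyad(base_pose(), base_pose() + 1,
                                              T_ = 300)), "too short")
  # metadata flows through; segments are consecutive
  expect_equal(clips[[3]]$condition, "mirroring")
  expect_match(clips[[3]]$dyad_id, "seg03")
})

test_that("counterbalance_assign balances cells overall and within leaders", {
  pool <- make_pool_df(8, n_leaders = 1)
  out <- counterbalance_assign(pool, seed = 5)
  cells <- table(out$leader_color, out$leader_side)
  expect_true(all(cells == 2))

  pool198 <- make_pool_df(198, n_leaders = 16)
  out198 <- counterbalance_assign(pool198, seed = 9)
  expect_equal(sum(out198$leader_color == "red"), 99)
  expect_equal(sum(out198$leader_side == "left"), 99)
  cells <- table(paste(out198$leader_color, out198$leader_side))
  expect_lte(max(cells) - min(cells), 1)
  # within each leader, cells differ by at most 1
  for (ld in unique(out198$leader_id)) {
    sub <- out198[out198$leader_id == ld, ]
    tab <- table(factor(paste(sub$leader_color, sub$leader_side),
                        levels = c("red left", "red right",
                                   "blue left", "blue right")))
    expect_lte(max(tab) - min(tab), 1)
  }
  # determinism
  expect_identical(out198, counterbalance_assign(pool198, seed = 9))
  expect_false(identical(out198$leader_color,
                         counterbalance_assign(pool198, seed = 10)$leader_color))
})

test_that("split_subsets meets size, overlap, leader, and cell constraints", {
  pool <- counterbalance_assign(make_pool_df(198, 16), seed = 3)
  out <- split_subsets(pool, seed = 3)
  nA <- sum(out$subset %in% c("A", "both"))
  nB <- sum(out$subset %in% c("B", "both"))
  expect_equal(nA, 100); expect_equal(nB, 100)
  expect_equal(sum(out$subset == "both"), 2)
  # every leader appears in both subsets
  for (ld in unique(out$leader_id)) {
    sub <- out$subset[out$leader_id == ld]
    expect_true(any(sub %in% c("A", "both")))
    expect_true(any(sub %in% c("B", "both")))
  }
  # per-leader unique clips split evenly
  for (ld in unique(out$leader_id)) {
    sub <- out$subset[out$leader_id == ld & out$subset != "both"]
    expect_lte(abs(sum(sub == "A") - sum(sub == "B")), 1)
  }
  # colour-by-side cells balanced within 1 between the subsets
  uni <- out[out$subset != "both", ]
  for (cell in unique(paste(uni$leader_color, uni$leader_side))) {
    sel <- paste(uni$leader_color, uni$leader_side) == cell
    expect_lte(abs(sum(uni$subset[sel] == "A") - sum(uni$subset[sel] == "B")), 1)
  }
  expect_identical(out, split_subsets(pool, seed = 3))
  expect_error(split_subsets(pool[1:100, ], seed = 1), "incompatible")
})

test_that("split_subsets invariants hold across many seeds and pool shapes", {
  for (s in 1:25) {
    withr::local_seed(s)
    n_leaders <- sample(3:16, 1)
    n <- 2 * sample(20:99, 1) # even pool
    overlap <- 2
    pool <- counterbalance_assign(make_pool_df(n, n_leaders), seed = s)
    out <- split_subsets(pool, overlap = overlap,
                         subset_size = (n - overlap) / 2 + overlap, seed = s)
    expect_equal(sum(out$subset %in% c("A", "both")),
                 sum(out$subset %in% c("B", "both")))
    expect_equal(sum(out$subset == "both"), overlap)
    for (ld in unique(out$leader_id)) {
      sub <- out$subset[out$leader_id == ld & out$subset != "both"]
      expect_lte(abs(sum(sub == "A") - sum(sub == "B")), 1)
    }
    uni <- out[out$subset != "both", ]
    cellkey <- paste(uni$leader_color, uni$leader_side)
    for (cell in unique(cellkey)) {
      sel <- cellkey == cell
      expect_lte(abs(sum(uni$subset[sel] == "A") - sum(uni$subset[sel] == "B")), 1)
    }
  }
})

test_that("build_trial_schedule produces the 153-trial structure", {
  pool <- make_pool_df(100)
  sched <- build_trial_schedule(pool, "P001", seed = 4)
  expect_equal(nrow(sched), 153)
  expect_equal(sum(sched$question == "attention"), 3)
  real <- sched[sched$question != "attention", ]
  expect_equal(nrow(real), 150)
  tab <- table(real$clip_id, real$question)
  expect_equal(dim(tab), c(50L, 3L))
  expect_true(all(tab == 1)) # each clip once per question
  expect_identical(sched, build_trial_schedule(pool, "P001", seed = 4))
  expect_error(build_trial_schedule(make_pool_df(10), n_videos = 50, seed = 1),
               "at least")
  # toy subset: 3n + 3 trials
  expect_equal(nrow(build_trial_schedule(make_pool_df(5), n_videos = 2,
                                         seed = 2)), 9)
})

test_that("trial-schedule invariants hold for 1000 random seeds", {
  pool <- make_pool_df(100)
  for (s in 1:1000) {
    sched <- build_trial_schedule(pool, "P", seed = s)
    att <- which(sched$question == "attention")
    expect_length(att, 3)
    expect_true(all(diff(att) > 1)) # never adjacent
    expect_equal(nrow(sched), 153)
    real <- sched$clip_id[sched$question != "attention"]
    expect_equal(length(unique(real)), 50)
    expect_true(all(table(real) == 3))
    expect_equal(sched$position, 1:153)
  }
})

test_that("score_attention applies the [0, 25] rule and 2-of-3 inclusion", {
  r <- score_attention(c(5, 30, 10))
  expect_equal(r$n_correct, 2); expect_true(r$included)
  expect_true(score_attention(c(0, 0, 0))$included)
  r3 <- score_attention(c(40, 30, 50))
  expect_equal(r3$n_correct, 0); expect_false(r3$included)
  expect_equal(score_attention(c(25, 25, 26))$n_correct, 2) # boundary closed
  expect_false(score_attention(c(26, 26, 0))$included)
  expect_error(score_attention(c(5, 10)), "exactly 3")
  expect_error(score_attention(c(5, 10, 101)), "0, 100")
})
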