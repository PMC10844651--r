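test_that("read_openpose_frames extracts 7 upper-body joints per person", {
  dir <- withr::local_tempdir()
  pa <- base_pose(); pb <- base_pose() + 300
  write_openpose_fixture(dir, list(list(pa, pb), list(pa, pb), list(pa, pb)))
  frames <- read_openpose_frames(dir)
  expect_length(frames, 3)
  for (f in frames) {
    expect_length(f, 2)
    expect_equal(dim(f[[1]]), c(7, 3))
    expect_equal(rownames(f[[1]]), dyad_joints())
  }
  # BODY_25 extraction: the neck row carries the coordinates we wrote
  expect_equal(unname(frames[[1]][[1]]["neck", c("x", "y")]), c(0, 0))
  expect_equal(unname(frames[[1]][[1]]["r_hand", c("x", "y")]),
               unname(pa["r_hand", ]))
})

test_that("read_openpose_frames error paths", {
  empty <- withr::local_tempdir()
  expect_error(read_openpose_frames(empty), "no frames")

  bad <- withr::local_tempdir()
  writeLines("{not json", file.path(bad, "frame_000000.json"))
  expect_error(read_openpose_frames(bad), "frame_000000")

  crowd <- withr::local_tempdir()
  write_openpose_fixture(crowd, list(list(base_pose(), base_pose() + 100,
                                          base_pose() + 200)))
  expect_error(read_openpose_frames(crowd), "dyads")
})

test_that("a missing person becomes an all-zero-confidence entry", {
  dir <- withr::local_tempdir()
  write_openpose_fixture(dir, list(list(base_pose())))
  frames <- read_openpose_frames(dir)
  expect_length(frames[[1]], 2)
  expect_true(all(frames[[1]][[2]][, "confidence"] == 0))
})

test_that("assemble_dyad tracks people by horizontal position", {
  dir <- withr::local_tempdir()
  left <- base_pose(); right <- base_pose() + cbind(rep(400, 7), 0)
  # person order shuffled across frames; sides never cross
  write_openpose_fixture(dir, list(list(left, right), list(right, left),
                                   list(left, right), list(right, left)))
  rec <- assemble_dyad(read_openpose_frames(dir), fps = 60)
  expect_equal(n_frames(rec), 4)
  expect_true(all(rec$series_a$coords[, , 1] < rec$series_b$coords[, , 1]))
  # stable assignment: series_a is always the left figure
  for (t in 1:4) expect_equal(rec$series_a$coords[t, 1, 1],
                              unname(left["neck", 1]))
})

test_that("assemble_dyad is invariant to frame-file enumeration order", {
  poses <- lapply(1:5, function(i) {
    list(base_pose() + i, base_pose() + cbind(rep(400, 7), 0) + i)
  })
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_openpose_fixture(d1, poses)
  # same frame -> file mapping, but files created in reversed order
  write_openpose_fixture(d2, rev(poses),
                         fnames = sprintf("frame_%06d_keypoints.json", 4:0))
  r1 <- assemble_dyad(read_openpose_frames(d1))
  r2 <- assemble_dyad(read_openpose_frames(d2))
  expect_equal(r1$series_a$coords, r2$series_a$coords)
})

test_that("assemble_dyad handles single frames and counts frames", {
  dir <- withr::local_tempdir()
  write_openpose_fixture(dir, list(list(base_pose(), base_pose() + 300)))
  rec <- assemble_dyad(read_openpose_frames(dir))
  expect_equal(n_frames(rec), 1)
  expect_error(assemble_dyad(list()), "at least one frame")
})

test_that("interpolate_gaps fills only short interior gaps", {
  coords <- array(0, c(5, 7, 2))
  conf <- matrix(1, 5, 7)
  # joint 1: linear motion with frame 2 missing; values 0, ?, 2, 3, 4
  coords[, 1, 1] <- c(0, 99, 2, 3, 4)
  coords[, 1, 2] <- c(0, 99, 2, 3, 4)
  conf[2, 1] <- 0
  s <- make_series(coords, conf = conf)
  out <- interpolate_gaps(s, max_gap_frames = 1)
  expect_equal(out$coords[2, 1, 1], 1)   # linear midpoint between 0 and 2
  expect_equal(out$conf[2, 1], 0.5)      # flagged as interpolated
  # everything outside the gap untouched
  expect_equal(out$coords[-2, , ], s$coords[-2, , ])
  expect_equal(out$coords[2, -1, ], s$coords[2, -1, ])

  # gap longer than max_gap_frames stays
  conf2 <- matrix(1, 5, 7); conf2[2:3, 1] <- 0
  s2 <- make_series(coords, conf = conf2)
  out2 <- interpolate_gaps(s2, max_gap_frames = 1)
  expect_identical(out2$coords, s2$coords)
  expect_identical(out2$conf, s2$conf)

  # gap-free series: bitwise identity
  s3 <- make_series(coords)
  expect_identical(interpolate_gaps(s3, 5), s3)
})

test_that("timeseries CSV round-trips coordinates and metadata", {
  rec <- simulate_dyad(dyad_sim_config("low", seed = 8), dyad_id = "dy1",
                       leader_id = "L07")
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(rec, f)
  rec2 <- read_timeseries_csv(f)
  expect_lt(max(abs(rec$series_a$coords - rec2$series_a$coords)), 1e-9)
  expect_lt(max(abs(rec$series_b$coords - rec2$series_b$coords)), 1e-9)
  expect_equal(rec2$series_a$conf, rec$series_a$conf)
  expect_equal(rec2$dyad_id, "dy1")
  expect_equal(rec2$leader_id, "L07")
  expect_equal(rec2$condition, "observing")
  expect_equal(rec2$series_a$fps, 60)
})

test_that("CSV reader reorders shuffled joints and validates schema", {
  rec <- make_static_dyad(base_pose(), base_pose() + 300, T_ = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(rec, f)
  lines <- readLines(f)
  body <- lines[-(1:2)]
  shuffled <- c(lines[1:2], sample(body)) # rows in random order
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuffled, f2)
  rec2 <- read_timeseries_csv(f2)
  expect_equal(rec2$series_a$coords, rec$series_a$coords)

  df <- utils::read.csv(f, comment.char = "#")
  df$confidence <- NULL
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f3, row.names = FALSE)
  expect_error(read_timeseries_csv(f3), "confidence")
})
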