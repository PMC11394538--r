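# Convenience: run a noiseless single-object scenario through the tracker.
static_sequence <- function(n_frames, box = c(100, 100, 40, 30)) {
  data.frame(frame = seq_len(n_frames), l = box[1], t = box[2],
             w = box[3], h = box[4], conf = 1)
}
static_embeddings <- function(n_frames, identity = 1) {
  matrix(rep(mock_embed(identity, 0), n_frames), nrow = n_frames,
         byrow = TRUE)
}

test_that("extreme ID value is the ceiling of the buffer mean", {
  expect_identical(extreme_id_value(c(7, 7, 7, 7, 7)), 7L)
  expect_identical(extreme_id_value(c(7, 7, 7, 8, 8)), 8L)   # mean 7.4
  expect_identical(extreme_id_value(1L), 1L)                 # partial window
  expect_error(extreme_id_value(integer(0)), "empty")
})

test_that("admission gate compares the candidate id with the extreme value", {
  st <- tracker_create(tracker_config())
  st$frame_count <- 10L
  st$max_id_history <- rep(4L, 5)
  st$next_id <- 4L
  adm <- admit_new_track(st, c(0, 0, 10, 10))
  expect_true(adm$created)                       # 4 <= 4, inclusive default
  st$next_id <- 5L
  adm <- admit_new_track(st, c(0, 0, 10, 10))
  expect_false(adm$created)                      # 5 > 4
  # strict comparison refuses equality
  st$config <- tracker_config(admission_strict = TRUE)
  st$next_id <- 4L
  adm <- admit_new_track(st, c(0, 0, 10, 10))
  expect_false(adm$created)
  # disabled gate always creates
  st$config <- tracker_config(admission_gate_enabled = FALSE)
  st$next_id <- 99L
  adm <- admit_new_track(st, c(0, 0, 10, 10))
  expect_true(adm$created)
  # partial ring buffer leaves the gate inactive
  st$config <- tracker_config()
  st$max_id_history <- c(4L, 4L)
  st$next_id <- 99L
  adm <- admit_new_track(st, c(0, 0, 10, 10))
  expect_true(adm$created)
})

test_that("a noiseless single object confirms after n_init matches", {
  dets <- static_sequence(5)
  emb <- static_embeddings(5)
  out <- track_sequence(dets, emb, tracker_config(), return_state = TRUE)
  expect_equal(unique(out$result$id), 1L)
  expect_equal(out$result$frame, 3:5)   # emitted once confirmed at frame 3
  gt <- dets; gt$id <- 1L
  ev <- suppressWarnings(evaluate_tracking(gt, out$result))
  expect_equal(unname(ev$summary["IDS"]), 0)
})

test_that("confirmed tracks are deleted after max_age consecutive misses", {
  cfg <- tracker_config(max_age = 5)
  state <- tracker_create(cfg)
  for (f in 1:4) {
    step <- tracker_step(state, matrix(c(10, 10, 20, 20), 1),
                         det_conf = 1,
                         det_emb = matrix(mock_embed(1, 0), 1), frame = f)
    state <- step$state
  }
  expect_equal(state$tracks[[1]]$status, "confirmed")
  for (f in 5:10) {
    step <- tracker_step(state, NULL, frame = f)
    state <- step$state
  }
  expect_equal(length(state$tracks), 0L)   # deleted at time_since_update 6 > 5
})

test_that("a tentative track dies on its first miss", {
  state <- tracker_create(tracker_config())
  step <- tracker_step(state, matrix(c(10, 10, 20, 20), 1), det_conf = 1,
                       det_emb = matrix(mock_embed(1, 0), 1), frame = 1)
  state <- step$state
  expect_equal(state$tracks[[1]]$status, "tentative")
  step <- tracker_step(state, NULL, frame = 2)
  expect_equal(length(step$state$tracks), 0L)
})

test_that("cascade matching prefers recently updated tracks", {
  cfg <- tracker_config()
  e <- mock_embed(1, 0)
  mk_track <- function(id, tsu) {
    tr <- list(id = id, status = "confirmed",
               kf = kf_initiate(tlwh_to_xyah(c(100, 100, 40, 30))),
               gallery = matrix(e, 1), hits = 5L, age = 10L,
               time_since_update = tsu, conf = 1)
    tr$kf <- kf_predict(tr$kf)
    tr
  }
  tracks <- list(mk_track(1L, 5L), mk_track(2L, 1L))
  res <- cascade_match(tracks, matrix(c(100, 100, 40, 30), 1),
                       matrix(e, 1), cfg)
  expect_equal(unname(res$matches[, 1]), 2L)   # the age-1 track wins
  expect_equal(res$unmatched_tracks, 1L)
})

test_that("cascade rejects appearance costs beyond the gate", {
  cfg <- tracker_config(max_cosine_distance = 0.2)
  e1 <- mock_embed(1, 0); e2 <- mock_embed(2, 0)   # distance ~1
  tr <- list(id = 1L, status = "confirmed",
             kf = kf_predict(kf_initiate(tlwh_to_xyah(c(0, 0, 10, 10)))),
             gallery = matrix(e1, 1), hits = 5L, age = 5L,
             time_since_update = 1L, conf = 1)
  res <- cascade_match(list(tr), matrix(c(0, 0, 10, 10), 1),
                       matrix(e2, 1), cfg)
  expect_equal(nrow(res$matches), 0L)
  expect_error(cascade_match(list(tr), matrix(c(0, 0, 10, 10), 1),
                             NULL, cfg), "embeddings")
})

test_that("IOU matching honours primary and relaxed gates", {
  tr <- list(id = 1L, status = "confirmed",
             kf = kf_initiate(tlwh_to_xyah(c(0, 0, 10, 10))),
             gallery = NULL, hits = 3L, age = 3L, time_since_update = 1L,
             conf = 1)
  # same box: matched at any gate
  res <- iou_match(list(tr), matrix(c(0, 0, 10, 10), 1), gate = 0.7)
  expect_equal(nrow(res$matches), 1L)
  # a pair with IoU 0.2 (cost 0.8): only the relaxed gate admits it
  b <- c(0, 0, 10, 10)
  shifted <- c(20 / 3, 0, 10, 10)   # IoU = (10-20/3)*10 / (2*100 - ...) = 0.2
  expect_equal(box_iou(b, shifted), 0.2, tolerance = 1e-9)
  res7 <- iou_match(list(tr), matrix(shifted, 1), gate = 0.7)
  expect_equal(nrow(res7$matches), 0L)
  res9 <- iou_match(list(tr), matrix(shifted, 1), gate = 0.9)
  expect_equal(nrow(res9$matches), 1L)
  # no detections
  res0 <- iou_match(list(tr), NULL, gate = 0.7)
  expect_equal(res0$unmatched_tracks, 1L)
})

test_that("ids increase, are never reused, and are unique within a frame", {
  sim <- simulate_sequence(scenario_preset("distant_dense", n_frames = 120,
                                           seed = 31))
  out <- track_sequence(sim$detections, sim$embeddings,
                        tracker_config(admission_gate_enabled = FALSE),
                        n_frames = 120, return_state = TRUE)
  res <- out$result
  per_frame <- split(res$id, res$frame)
  expect_true(all(vapply(per_frame, anyDuplicated, 0L) == 0L))
  log <- admission_log(out$state)
  created_ids <- log$candidate_id[log$created]
  expect_true(all(diff(created_ids) > 0))   # strictly increasing, no reuse
})

test_that("the admission log certifies the extreme-ID bound on creations", {
  for (seed in c(5, 17)) {
    sim <- simulate_sequence(scenario_preset("distant_dense",
                                             n_frames = 150, seed = seed))
    out <- track_sequence(sim$detections, sim$embeddings, tracker_config(),
                          n_frames = 150, return_state = TRUE)
    log <- admission_log(out$state)
    gated <- log[log$gate_active, ]
    created <- gated[gated$created, ]
    if (nrow(created))
      expect_true(all(created$candidate_id <= created$extreme))
    refused <- gated[!gated$created, ]
    if (nrow(refused))
      expect_true(all(refused$candidate_id > refused$extreme))
  }
})

test_that("two crossing objects keep their identities through occlusion", {
  # two boxes crossing paths with a 2-frame overlap, noiseless appearance
  n <- 20
  dets <- NULL
  for (f in 1:n) {
    x1 <- 10 + 10 * (f - 1)            # left-to-right
    x2 <- 200 - 10 * (f - 1)           # right-to-left
    dets <- rbind(dets,
                  data.frame(frame = f, l = x1, t = 50, w = 30, h = 30,
                             conf = 1, src = 1),
                  data.frame(frame = f, l = x2, t = 50, w = 30, h = 30,
                             conf = 1, src = 2))
  }
  emb <- t(vapply(dets$src, function(i) mock_embed(i, 0), numeric(256)))
  res <- track_sequence(dets[, 1:6], emb, tracker_config(), n_frames = n)
  gt <- dets[, 1:6]; gt$id <- dets$src
  ev <- suppressWarnings(evaluate_tracking(gt, res))
  expect_equal(unname(ev$summary["IDS"]), 0)
  expect_equal(length(unique(res$id)), 2L)
})

test_that("disabling gate and secondary pass gives classic behaviour", {
  classic <- tracker_config(admission_gate_enabled = FALSE,
                            secondary_iou_enabled = FALSE)
  # every unmatched detection creates a track, regardless of id history
  state <- tracker_create(classic)
  state$max_id_history <- rep(1L, 5)
  state$next_id <- 50L
  adm <- admit_new_track(state, c(0, 0, 10, 10))
  expect_true(adm$created)
  # on an easy noiseless run both configurations coincide
  sim <- simulate_sequence(scenario_preset(
    "sparse", n_frames = 60, miss_prob_base = 0, miss_prob_occluded = 0,
    fp_rate = 0, jitter_sd = 0, embed_noise_sd = 0,
    embed_noise_occluded_sd = 0, seed = 2))
  r1 <- track_sequence(sim$detections, sim$embeddings, classic, n_frames = 60)
  r2 <- track_sequence(sim$detections, sim$embeddings, tracker_config(),
                       n_frames = 60)
  expect_identical(r1, r2)
})

test_that("out-of-order frames and invalid configs are rejected", {
  state <- tracker_create(tracker_config())
  step <- tracker_step(state, NULL, frame = 5)
  expect_error(tracker_step(step$state, NULL, frame = 4), "increasing")
  expect_error(tracker_config(secondary_iou_gate = 0.5,
                              primary_iou_gate = 0.7), ">=")
  expect_error(tracker_config(n_init = 0), "n_init")
})

test_that("low-confidence detections are dropped before matching", {
  cfg <- tracker_config(min_confidence = 0.3, admission_gate_enabled = FALSE)
  state <- tracker_create(cfg)
  step <- tracker_step(state, rbind(c(0, 0, 10, 10), c(50, 50, 10, 10)),
                       det_conf = c(0.9, 0.1),
                       det_emb = rbind(mock_embed(1, 0), mock_embed(2, 0)),
                       frame = 1)
  expect_equal(length(step$state$tracks), 1L)
})

test_that("classic configuration reproduces its reference traces bit-for-bit", {
  # regression against frozen traces of the gate-off, secondary-off
  # configuration on three occlusion-heavy fixture sequences
  classic <- tracker_config(secondary_iou_enabled = FALSE,
                            admission_gate_enabled = FALSE)
  for (seed in c(101, 102, 103)) {
    sim <- simulate_sequence(scenario_preset("distant_dense", n_frames = 60,
                                             seed = seed))
    res <- track_sequence(sim$detections, sim$embeddings, classic,
                          n_frames = 60)
    f <- withr::local_tempfile()
    write_mot(res, f)
    golden <- testthat::test_path("fixtures",
                                  sprintf("classic_trace_seed%d.txt", seed))
    expect_identical(readLines(f), readLines(golden))
  }
})
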