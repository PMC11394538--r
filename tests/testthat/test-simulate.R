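test_that("the sequence is a pure function of its configuration", {
  cfg <- scenario_preset("sparse", n_frames = 40, seed = 123)
  s1 <- simulate_sequence(cfg)
  s2 <- simulate_sequence(cfg)
  expect_identical(s1$gt, s2$gt)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$embeddings, s2$embeddings)
})

test_that("zero speed and zero event rate give static ground truth", {
  cfg <- scenario_config(n_animals = 3, n_frames = 10, speed_sd = 0,
                         occlusion_event_rate = 0, seed = 5)
  set.seed(cfg$seed)
  truth <- generate_truth(cfg)
  first <- truth$gt[truth$gt$frame == 1, c("id", "l", "t", "w", "h")]
  for (f in 2:10) {
    cur <- truth$gt[truth$gt$frame == f, c("id", "l", "t", "w", "h")]
    rownames(cur) <- rownames(first) <- NULL
    expect_identical(cur, first)
  }
})

test_that("every animal is present in every frame (enclosed pen)", {
  sim <- simulate_sequence(scenario_preset("distant_dense", n_frames = 80,
                                           seed = 2))
  counts <- table(sim$gt$frame)
  expect_true(all(counts == 7))
  expect_true(all(sim$gt$l >= 0 & sim$gt$t >= 0))
  expect_true(all(sim$gt$l + sim$gt$w <= 1280 + 1e-6))
  expect_true(all(sim$gt$t + sim$gt$h <= 720 + 1e-6))
})

test_that("occlusion events produce logged intervals with IoU >= 0.5", {
  cfg <- scenario_preset("distant_dense", n_frames = 500, seed = 8)
  sim <- simulate_sequence(cfg)
  occ <- sim$occlusions
  expect_gt(nrow(occ), 0)
  for (k in seq_len(min(nrow(occ), 5))) {
    f <- occ$start[k]
    g <- sim$gt[sim$gt$frame == f, ]
    ba <- as.numeric(g[g$id == occ$id_a[k], c("l", "t", "w", "h")])
    bb <- as.numeric(g[g$id == occ$id_b[k], c("l", "t", "w", "h")])
    expect_gte(box_iou(ba, bb), 0.5)
  }
})

test_that("detector noise respects its degenerate limits", {
  cfg0 <- scenario_preset("sparse", n_frames = 15, miss_prob_base = 0,
                          miss_prob_occluded = 0, fp_rate = 0,
                          jitter_sd = 0, seed = 3)
  sim <- simulate_sequence(cfg0)
  expect_equal(nrow(sim$detections), nrow(sim$gt))
  expect_true(all(sim$detections$conf == 1))
  expect_equal(sim$detections$l, sim$gt$l)
  # certain misses leave only false positives
  cfg1 <- scenario_preset("sparse", n_frames = 15, miss_prob_base = 1,
                          miss_prob_occluded = 1, seed = 3)
  sim1 <- simulate_sequence(cfg1)
  expect_true(all(is.na(sim1$detections$src_id)))
})

test_that("false-positive counts follow the configured Poisson rate", {
  cfg <- scenario_preset("sparse", n_frames = 1000, fp_rate = 0.5, seed = 21)
  sim <- simulate_sequence(cfg)
  n_fp <- sum(is.na(sim$detections$src_id))
  total <- stats::qpois(c(0.005, 0.995), 0.5 * 1000)
  expect_gte(n_fp, total[1])
  expect_lte(n_fp, total[2])
})

test_that("embeddings separate identities and degrade under occlusion", {
  cfg <- scenario_preset("distant_dense", n_frames = 200, seed = 13)
  sim <- simulate_sequence(cfg)
  det <- sim$detections
  emb <- sim$embeddings
  true_rows <- which(!is.na(det$src_id) & !det$occluded)
  # within- vs between-identity cosine distances on a sample
  set.seed(1)
  rows <- sample(true_rows, 300, replace = TRUE)
  anchors <- t(vapply(det$src_id[rows], function(i) mock_embed(i, 0),
                      numeric(256)))
  within <- 1 - rowSums(emb[rows, ] * anchors)
  other <- t(vapply(det$src_id[rows] %% cfg$n_animals + 1L,
                    function(i) mock_embed(i, 0), numeric(256)))
  between <- 1 - rowSums(emb[rows, ] * other)
  expect_lt(mean(within), mean(between))
  expect_lt(mean(within), 0.1)
  occ_rows <- which(det$occluded)
  if (length(occ_rows) > 10) {
    anchors_o <- t(vapply(det$src_id[occ_rows], function(i) mock_embed(i, 0),
                          numeric(256)))
    occl_d <- 1 - rowSums(emb[occ_rows, ] * anchors_o)
    expect_gt(mean(occl_d), mean(within))
  }
})

test_that("written sequences round-trip through the MOT readers", {
  sim <- simulate_sequence(scenario_preset("sparse", n_frames = 20, seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_sequence(sim, dir)
  gt <- read_mot(paths[["gt"]], "gt")
  expect_equal(nrow(gt), nrow(sim$gt))
  det <- read_mot(paths[["det"]], "det")
  expect_equal(nrow(det), nrow(sim$detections))
  emb <- read_feature_sidecar(paths[["features"]], nrow(det))
  expect_equal(dim(emb), dim(sim$embeddings))
  # sidecar rows align with detection lines after the sorted write
  expect_equal(emb[1, ], sim$embeddings[1, ], tolerance = 1e-6)
  expect_true(any(grepl("seed=6", readLines(paths[["truth_log"]]))))
})

test_that("invalid scenario configurations are rejected", {
  expect_error(scenario_config(n_animals = 0), "n_animals")
  expect_error(scenario_config(miss_prob_base = 0.5, miss_prob_occluded = 0.1),
               "miss_prob_occluded")
  expect_error(scenario_config(n_animals = 50, arena = c(100, 100)),
               "arena")
})
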