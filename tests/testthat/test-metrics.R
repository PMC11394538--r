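mk_acc <- function(GT = 0L, FP = 0L, FN = 0L, IDS = 0L, iou_sum = 0,
                   match_count = 0L, total_hyp = 0L) {
  acc <- new_accumulator()
  acc$GT <- GT; acc$FP <- FP; acc$FN <- FN; acc$IDS <- IDS
  acc$iou_sum <- iou_sum; acc$match_count <- match_count
  acc$total_hyp <- total_hyp
  acc
}

test_that("MOTA follows its defining formula, including negative values", {
  expect_equal(mota(mk_acc(GT = 10L)), 1)
  expect_equal(mota(mk_acc(GT = 100L, FN = 5L, FP = 3L, IDS = 2L)), 0.9)
  expect_equal(mota(mk_acc(GT = 10L, FN = 10L, FP = 10L)), -1)
  expect_error(mota(mk_acc(GT = 0L)), "undefined")
})

test_that("MOTP is the mean IoU of successful matches", {
  expect_equal(motp(mk_acc(iou_sum = 0.8, match_count = 1L, GT = 1L)), 0.8)
  expect_equal(motp(mk_acc(iou_sum = 1.6, match_count = 2L, GT = 2L)), 0.8)
  expect_error(motp(mk_acc(GT = 1L)), "undefined")
})

test_that("IDF1 follows its defining formula", {
  # IDTP 90, IDFP 10, IDFN 10 -> 0.9
  acc <- mk_acc(GT = 100L, total_hyp = 100L)
  acc$id_overlap <- list("1\r2" = 90L)
  expect_equal(idf1(acc), 0.9)
  expect_error(idf1(mk_acc(GT = 0L)), "undefined")
})

test_that("frame matching handles identity, misses and id switches", {
  b <- c(0, 0, 10, 10)
  fr <- match_frame(rbind(b), 1L, rbind(b), 7L)
  expect_equal(nrow(fr$matches), 1L)
  expect_equal(fr$matches$iou, 1)
  fr <- match_frame(rbind(b), 1L, NULL, integer(0))
  expect_equal(fr$false_negatives, 1L)
  # switch: gt 1 matched to hyp 7 then hyp 8
  acc <- new_accumulator()
  acc <- accumulate_frame(acc, rbind(b), 1L, rbind(b), 7L)
  acc <- accumulate_frame(acc, rbind(b), 1L, rbind(b), 8L)
  expect_equal(acc$IDS, 1L)
  expect_error(match_frame(rbind(b, b), c(1L, 1L), NULL, integer(0)),
               "duplicate")
})

test_that("carry-over keeps a previous pair even against a higher-IoU rival", {
  # gt 1 was matched to hyp 7; a new hyp 8 overlaps slightly better,
  # but the previous correspondence persists while above threshold
  gt_b <- c(0, 0, 10, 10)
  h7 <- c(1, 0, 10, 10); h8 <- c(0.5, 0, 10, 10)
  acc <- new_accumulator()
  acc <- accumulate_frame(acc, rbind(gt_b), 1L, rbind(h7), 7L)
  fr <- match_frame(rbind(gt_b), 1L, rbind(h7, h8), c(7L, 8L),
                    prev = acc$last_hyp)
  expect_equal(fr$matches$hyp, 7L)
  expect_false(fr$matches$switch)
})

test_that("evaluation of a perfect result is perfect", {
  sim <- simulate_sequence(scenario_preset("sparse", n_frames = 30, seed = 4))
  gt <- sim$gt; gt$conf <- 1
  ev <- evaluate_tracking(gt, gt)
  expect_equal(unname(ev$summary),
               c(1, 0, 1, 1))
})

test_that("warm-up style gaps reduce MOTA by exactly the missed boxes", {
  gt <- data.frame(frame = 1:10, id = 1L, l = 0, t = 0, w = 10, h = 10,
                   conf = 1)
  res <- gt[gt$frame >= 3, ]
  ev <- suppressWarnings(evaluate_tracking(gt, res))
  expect_equal(unname(ev$summary["MOTA"]), 0.8)   # FN = 2, GT = 10
  expect_equal(unname(ev$summary["IDS"]), 0)
})

test_that("random small instances agree with the enumeration oracle", {
  set.seed(314)
  for (rep in 1:60) {
    inst <- random_instance(n_obj = sample(1:3, 1),
                            n_frames = sample(2:4, 1))
    if (is.null(inst$gt) || is.null(inst$hyp)) next
    ev <- suppressWarnings(evaluate_tracking(inst$gt, inst$hyp))
    orc <- oracle_clearmot(inst$gt, inst$hyp)
    expect_equal(unname(ev$summary["MOTA"]), orc$MOTA, tolerance = 1e-12)
    expect_equal(unname(ev$summary["IDS"]), orc$IDS)
    expect_equal(unname(ev$summary["IDF1"]), orc$IDF1, tolerance = 1e-12)
    if (!is.na(orc$MOTP))
      expect_equal(unname(ev$summary["MOTP"]), orc$MOTP, tolerance = 1e-12)
  }
})

test_that("MOTP is invariant to frame order; MOTA falls as FPs are injected", {
  sim <- simulate_sequence(scenario_preset("sparse", n_frames = 20, seed = 9))
  gt <- sim$gt; gt$conf <- 1
  perm <- sample(unique(gt$frame))
  remap <- stats::setNames(seq_along(perm), perm)
  gt2 <- gt; gt2$frame <- as.integer(remap[as.character(gt$frame)])
  ev1 <- evaluate_tracking(gt, gt)
  ev2 <- evaluate_tracking(gt2, gt2)
  expect_equal(ev1$summary["MOTP"], ev2$summary["MOTP"])
  # inject false positives progressively
  motas <- vapply(c(0, 10, 25), function(k) {
    res <- gt
    if (k > 0) {
      fp <- data.frame(frame = rep(1:20, length.out = k),
                       id = 990L + seq_len(k),
                       l = 1500, t = 900, w = 20, h = 20, conf = 1)
      res <- rbind(gt, fp)
    }
    unname(suppressWarnings(evaluate_tracking(gt, res))$summary["MOTA"])
  }, 0)
  expect_true(all(diff(motas) < 0))
})
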