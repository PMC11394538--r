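#' CLEAR-MOT and identity metrics
#'
#' Frame-by-frame correspondence between ground truth and hypotheses
#' follows the CLEAR-MOT protocol: pairs matched in the previous frame
#' are kept while they still overlap at least the IoU threshold, the
#' remainder are matched by a min-cost assignment maximising total IoU
#' subject to the threshold, and leftovers count as misses (FN) and
#' false positives (FP).  An identity switch (IDS) is flagged whenever
#' a ground-truth object's matched hypothesis id differs from its last
#' matched hypothesis id.  From the accumulated counters:
#' \deqn{MOTA = 1 - (FN + FP + IDS)/GT}
#' \deqn{MOTP = \sum_{i,t} d_{i,t} / \sum_t c_t}
#' with `d` the IoU of each successful match and `c_t` the per-frame
#' match count (higher is better), and IDF1 the F1 score of
#' identity-consistent detection under the optimal global one-to-one
#' mapping of ground-truth to hypothesis identities:
#' \deqn{IDF1 = 2\,IDTP / (2\,IDTP + IDFP + IDFN).}
#'
#' @name mot_metrics
NULL

#' Create an empty metrics accumulator
#'
#' @return A `mot_accumulator` list of counters: `GT`, `FP`, `FN`,
#'   `IDS`, `iou_sum`, `match_count`, `total_hyp`, the identity
#'   co-occurrence table and the last-hypothesis map.
#' @export
new_accumulator <- function() {
  structure(list(GT = 0L, FP = 0L, FN = 0L, IDS = 0L,
                 iou_sum = 0, match_count = 0L, total_hyp = 0L,
                 id_overlap = list(), last_hyp = integer(0)),
            class = "mot_accumulator")
}

#' Match one frame's ground truth against hypotheses
#'
#' @param gt_boxes,hyp_boxes tlwh box matrices (possibly 0-row).
#' @param gt_ids,hyp_ids integer ids, unique within each side.
#' @param prev named integer vector: last matched hypothesis id per
#'   ground-truth id (names are gt ids).
#' @param iou_threshold minimum IoU for a valid correspondence
#'   (default 0.5, the MOT-16 convention).
#' @return A list: `matches` data.frame (`gt, hyp, iou, switch`),
#'   `false_negatives` (gt ids), `false_positives` (hyp ids).
#' @export
match_frame <- function(gt_boxes, gt_ids, hyp_boxes, hyp_ids,
                        prev = integer(0), iou_threshold = 0.5) {
  n_gt <- length(gt_ids); n_hyp <- length(hyp_ids)
  if (anyDuplicated(gt_ids)) stop("duplicate ground-truth ids in frame")
  if (anyDuplicated(hyp_ids)) stop("duplicate hypothesis ids in frame")
  gt_boxes <- if (n_gt) as_box_matrix(gt_boxes) else
    matrix(numeric(0), 0L, 4L)
  hyp_boxes <- if (n_hyp) as_box_matrix(hyp_boxes) else
    matrix(numeric(0), 0L, 4L)
  iou <- box_iou_matrix(gt_boxes, hyp_boxes)

  pairs <- NULL
  free_gt <- seq_len(n_gt); free_hyp <- seq_len(n_hyp)
  # carry-over: keep still-valid previous correspondences
  if (length(prev)) {
    for (gi in seq_len(n_gt)) {
      ph <- prev[as.character(gt_ids[gi])]
      if (is.na(ph)) next
      hi <- match(ph, hyp_ids)
      if (is.na(hi) || !(hi %in% free_hyp)) next
      if (iou[gi, hi] >= iou_threshold) {
        pairs <- rbind(pairs, c(gi, hi))
        free_gt <- setdiff(free_gt, gi)
        free_hyp <- setdiff(free_hyp, hi)
      }
    }
  }
  # remaining: min-cost assignment maximising total IoU over the gate
  if (length(free_gt) && length(free_hyp)) {
    cost <- 1 - iou[free_gt, free_hyp, drop = FALSE]
    cost[cost > 1 - iou_threshold] <- Inf
    sol <- solve_assignment(cost, gate = 1 - iou_threshold)
    if (nrow(sol$matches)) {
      pairs <- rbind(pairs, cbind(free_gt[sol$matches[, 1L]],
                                  free_hyp[sol$matches[, 2L]]))
      free_gt <- free_gt[sol$unmatched_rows]
      free_hyp <- free_hyp[sol$unmatched_cols]
    }
  }
  if (is.null(pairs)) {
    matches <- data.frame(gt = integer(0), hyp = integer(0),
                          iou = numeric(0), switch = logical(0))
  } else {
    g <- gt_ids[pairs[, 1L]]
    h <- hyp_ids[pairs[, 2L]]
    last <- unname(prev[as.character(g)])
    matches <- data.frame(gt = g, hyp = h, iou = iou[pairs],
                          switch = !is.na(last) & last != h)
    matches <- matches[order(matches$gt), , drop = FALSE]
    rownames(matches) <- NULL
  }
  list(matches = matches,
       false_negatives = gt_ids[free_gt],
       false_positives = hyp_ids[free_hyp])
}

#' Accumulate one frame into a metrics accumulator
#'
#' @param acc a `mot_accumulator`.
#' @param gt_boxes,gt_ids,hyp_boxes,hyp_ids the frame's annotations and
#'   hypotheses, as in [match_frame()].
#' @param iou_threshold correspondence threshold (default 0.5).
#' @return The updated accumulator.
#' @export
accumulate_frame <- function(acc, gt_boxes, gt_ids, hyp_boxes, hyp_ids,
                             iou_threshold = 0.5) {
  fr <- match_frame(gt_boxes, gt_ids, hyp_boxes, hyp_ids,
                    prev = acc$last_hyp, iou_threshold = iou_threshold)
  acc$GT <- acc$GT + length(gt_ids)
  acc$total_hyp <- acc$total_hyp + length(hyp_ids)
  acc$FN <- acc$FN + length(fr$false_negatives)
  acc$FP <- acc$FP + length(fr$false_positives)
  acc$IDS <- acc$IDS + sum(fr$matches$switch)
  acc$iou_sum <- acc$iou_sum + sum(fr$matches$iou)
  acc$match_count <- acc$match_count + nrow(fr$matches)
  if (nrow(fr$matches)) {
    for (k in seq_len(nrow(fr$matches))) {
      key <- paste(fr$matches$gt[k], fr$matches$hyp[k], sep = "\r")
      acc$id_overlap[[key]] <- (acc$id_overlap[[key]] %||% 0L) + 1L
    }
    lh <- acc$last_hyp
    lh[as.character(fr$matches$gt)] <- fr$matches$hyp
    acc$last_hyp <- lh
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiple object tracking accuracy
#'
#' `1 - (FN + FP + IDS)/GT`; can be negative, 1 is perfect.
#'
#' @param acc a `mot_accumulator` with `GT > 0`.
#' @return MOTA.
#' @export
mota <- function(acc) {
  if (acc$GT <= 0L) stop("MOTA undefined: no ground-truth boxes")
  1 - (acc$FN + acc$FP + acc$IDS) / acc$GT
}

#' Multiple object tracking precision (IoU form)
#'
#' Mean IoU of successful matches, `sum(d)/sum(c)`; higher is better.
#'
#' @param acc a `mot_accumulator` with at least one match.
#' @return MOTP in `[0, 1]`.
#' @export
motp <- function(acc) {
  if (acc$match_count <= 0L) stop("MOTP undefined: no matches")
  acc$iou_sum / acc$match_count
}

#' Identity F1 score
#'
#' Solves the global one-to-one mapping between ground-truth and
#' hypothesis identities maximising total co-occurrence; IDTP is the
#' co-occurrence captured by that mapping, IDFN = GT - IDTP,
#' IDFP = total hypothesis boxes - IDTP.
#'
#' @param acc a `mot_accumulator` with `GT > 0`.
#' @return IDF1 in `[0, 1]`.
#' @export
idf1 <- function(acc) {
  if (acc$GT <= 0L) stop("IDF1 undefined: no ground-truth boxes")
  idtp <- idf1_idtp(acc$id_overlap)
  idfn <- acc$GT - idtp
  idfp <- acc$total_hyp - idtp
  2 * idtp / (2 * idtp + idfp + idfn)
}

idf1_idtp <- function(id_overlap) {
  if (!length(id_overlap)) return(0L)
  keys <- strsplit(names(id_overlap), "\r", fixed = TRUE)
  gt <- vapply(keys, `[`, "", 1L)
  hyp <- vapply(keys, `[`, "", 2L)
  counts <- unlist(id_overlap, use.names = FALSE)
  gtu <- unique(gt); hypu <- unique(hyp)
  m <- matrix(0, length(gtu), length(hypu),
              dimnames = list(gtu, hypu))
  m[cbind(match(gt, gtu), match(hyp, hypu))] <- counts
  sol <- solve_assignment(-m)
  if (!nrow(sol$matches)) return(0L)
  sum(m[sol$matches])
}

#' Evaluate a tracking result against ground truth
#'
#' Frame-by-frame CLEAR-MOT accumulation over the union of frames
#' present in either table, then the metric closures.
#'
#' @param gt ground truth: path to a MOT-16 gt file or a data.frame
#'   with columns `frame, id, l, t, w, h`.
#' @param result hypotheses: path to a MOT-16 result file or an
#'   equivalent data.frame.
#' @param iou_threshold correspondence threshold (default 0.5).
#' @return A list: `summary` (named vector IDF1, IDS, MOTA, MOTP),
#'   `accumulator`, and `text` (the 3-decimal report line).
#' @export
evaluate_tracking <- function(gt, result, iou_threshold = 0.5) {
  if (is.character(gt)) gt <- read_mot(gt, kind = "gt")
  if (is.character(result)) result <- read_mot(result, kind = "result")
  if (!nrow(gt)) stop("ground truth is empty")
  gt_frames <- sort(unique(gt$frame))
  hyp_frames <- sort(unique(result$frame))
  if (!setequal(gt_frames, hyp_frames))
    warning("frame ranges differ between ground truth and result; ",
            "evaluating over their union")
  acc <- new_accumulator()
  gt_by <- split(seq_len(nrow(gt)), gt$frame)
  hyp_by <- split(seq_len(nrow(result)), result$frame)
  for (f in sort(union(gt_frames, hyp_frames))) {
    gi <- gt_by[[as.character(f)]]
    hi <- hyp_by[[as.character(f)]]
    acc <- accumulate_frame(
      acc,
      gt_boxes = if (length(gi)) as.matrix(gt[gi, c("l", "t", "w", "h")]) else NULL,
      gt_ids = if (length(gi)) gt$id[gi] else integer(0),
      hyp_boxes = if (length(hi)) as.matrix(result[hi, c("l", "t", "w", "h")]) else NULL,
      hyp_ids = if (length(hi)) result$id[hi] else integer(0),
      iou_threshold = iou_threshold)
  }
  summary <- c(IDF1 = idf1(acc), IDS = acc$IDS, MOTA = mota(acc),
               MOTP = if (acc$match_count > 0L) motp(acc) else NA_real_)
  text <- paste(mapply(function(n, v) {
    if (n == "IDS") sprintf("%s %d", n, as.integer(v))
    else sprintf("%s %.3f", n, v)
  }, names(summary), summary), collapse = "  ")
  list(summary = summary, accumulator = acc, text = text)
}
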