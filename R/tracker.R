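#' Improved Deep SORT tracker for fixed-count pens
#'
#' Per-frame association runs in three stages: (1) appearance cascade
#' over confirmed tracks, by ascending time-since-update, using the
#' minimum gallery cosine distance under a Mahalanobis motion gate;
#' (2) primary IOU matching over tentative tracks plus confirmed tracks
#' that just missed the cascade; (3) a secondary IOU pass over the
#' leftovers of stage 2 at a relaxed admissibility gate.  New tracks
#' are admitted through the "extreme ID" gate: in an enclosed pen the
#' herd size is fixed, so a candidate track id that exceeds the ceiling
#' of the mean of the last few frames' maximum ids is taken to be a
#' detector artefact and no track is created.
#'
#' @name tracker
NULL

#' Tracker configuration
#'
#' @param n_init consecutive matches (counting the initiating detection)
#'   required to confirm a tentative track (default 3).
#' @param max_age frames a confirmed track may go unmatched before
#'   deletion (default 30).
#' @param max_cosine_distance appearance gate for the cascade
#'   (default 0.2).
#' @param primary_iou_gate maximum cost `1 - IoU` admitted by the
#'   primary IOU stage (default 0.7).
#' @param secondary_iou_gate relaxed cost gate for the secondary IOU
#'   stage (default 0.9; must be >= `primary_iou_gate`).
#' @param gallery_budget appearance gallery size per track (default 100).
#' @param extreme_id_window frames over which per-frame maximum ids are
#'   averaged for the admission gate (default 5).
#' @param admission_gate_enabled enable the extreme-ID admission gate
#'   (default TRUE).
#' @param admission_strict if TRUE the candidate id must be strictly
#'   below the extreme ID value; the default FALSE admits equality.
#' @param secondary_iou_enabled enable the secondary IOU pass
#'   (default TRUE).  Disabling this and the admission gate reduces the
#'   tracker to classic Deep SORT behaviour.
#' @param secondary_scope which tracks enter the secondary pass:
#'   `"all_unmatched"` (default) admits every track still unmatched
#'   after the primary stage, including cascade-rejected confirmed
#'   tracks of any age — this is what lets a track starved through an
#'   occlusion burst reclaim its animal instead of dying;
#'   `"primary_leftovers"` restricts it to the primary IOU stage's own
#'   leftovers.
#' @param min_confidence detections below this confidence are dropped
#'   (default 0.3).
#' @param gating_threshold squared Mahalanobis gate for the cascade
#'   (default [chi2_gate()], the 0.95 chi-square quantile at 4 df).
#' @param weight_position,weight_velocity Kalman noise scales, see
#'   [kf_initiate()].
#' @param emit_tentative also emit tentative tracks (default FALSE).
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(n_init = 3L,
                           max_age = 30L,
                           max_cosine_distance = 0.2,
                           primary_iou_gate = 0.7,
                           secondary_iou_gate = 0.9,
                           gallery_budget = 100L,
                           extreme_id_window = 5L,
                           admission_gate_enabled = TRUE,
                           admission_strict = FALSE,
                           secondary_iou_enabled = TRUE,
                           secondary_scope = c("all_unmatched",
                                               "primary_leftovers"),
                           min_confidence = 0.3,
                           gating_threshold = chi2_gate(),
                           weight_position = 1 / 20,
                           weight_velocity = 1 / 160,
                           emit_tentative = FALSE) {
  cfg <- list(n_init = as.integer(n_init), max_age = as.integer(max_age),
              max_cosine_distance = max_cosine_distance,
              primary_iou_gate = primary_iou_gate,
              secondary_iou_gate = secondary_iou_gate,
              gallery_budget = as.integer(gallery_budget),
              extreme_id_window = as.integer(extreme_id_window),
              admission_gate_enabled = isTRUE(admission_gate_enabled),
              admission_strict = isTRUE(admission_strict),
              secondary_iou_enabled = isTRUE(secondary_iou_enabled),
              secondary_scope = match.arg(secondary_scope),
              min_confidence = min_confidence,
              gating_threshold = gating_threshold,
              weight_position = weight_position,
              weight_velocity = weight_velocity,
              emit_tentative = isTRUE(emit_tentative))
  if (cfg$n_init < 1L) stop("n_init must be >= 1")
  if (cfg$extreme_id_window < 1L) stop("extreme_id_window must be >= 1")
  if (cfg$secondary_iou_gate < cfg$primary_iou_gate)
    stop("secondary_iou_gate must be >= primary_iou_gate")
  class(cfg) <- "tracker_config"
  cfg
}

#' Create an empty tracker state
#'
#' @param config a [tracker_config()].
#' @return A `tracker_state` list: live tracks, the next id to assign,
#'   the ring buffer of recent per-frame maximum ids, the frame
#'   counter, and an admission log recording every new-track decision.
#' @export
tracker_create <- function(config = tracker_config()) {
  structure(list(tracks = list(), next_id = 1L, max_id_history = integer(0),
                 frame_count = 0L, config = config,
                 admission_log = list()),
            class = "tracker_state")
}

#' @export
print.tracker_state <- function(x, ...) {
  st <- vapply(x$tracks, function(t) t$status, "")
  cat("<tracker_state> frame", x$frame_count, "-",
      sum(st == "confirmed"), "confirmed,",
      sum(st == "tentative"), "tentative tracks; next id", x$next_id, "\n")
  invisible(x)
}

new_track <- function(id, det_box, embedding, conf, cfg) {
  list(id = id, status = "tentative",
       kf = kf_initiate(tlwh_to_xyah(det_box),
                        cfg$weight_position, cfg$weight_velocity),
       gallery = if (is.null(embedding)) NULL else
         gallery_append(NULL, l2_normalize(embedding), cfg$gallery_budget),
       hits = 1L, age = 1L, time_since_update = 0L, conf = conf)
}

track_tlwh <- function(track) xyah_to_tlwh(track$kf$mean[1:4])

#' Extreme ID value from the recent-maximum ring buffer
#'
#' The ceiling of the arithmetic mean of the per-frame maximum assigned
#' ids held in the buffer; an integer mean is returned unchanged
#' (ceiling of an integer is itself).
#'
#' @param history integer vector of recent per-frame maximum ids
#'   (most recent last); must be non-empty.
#' @return The extreme ID value (integer).
#' @export
extreme_id_value <- function(history) {
  if (!length(history)) stop("empty id history")
  as.integer(ceiling(mean(history)))
}

#' Decide admission of a new track for an unmatched detection
#'
#' With the gate disabled, or before the ring buffer has filled its
#' window, a tentative track is always created.  Otherwise the
#' candidate id (`next_id`) is compared with the extreme ID value: at
#' most equal (default) or strictly below (`admission_strict`);
#' candidates beyond the cap create nothing.
#'
#' @param state a `tracker_state`.
#' @param det_box box (tlwh) of the unmatched detection.
#' @param embedding optional appearance embedding of the detection.
#' @param conf detection confidence.
#' @return `list(state, created)` with the possibly-updated state.
#' @export
admit_new_track <- function(state, det_box, embedding = NULL, conf = 1) {
  cfg <- state$config
  gate_active <- cfg$admission_gate_enabled &&
    length(state$max_id_history) >= cfg$extreme_id_window
  extreme <- if (length(state$max_id_history))
    extreme_id_value(state$max_id_history) else NA_integer_
  admit <- if (!gate_active) TRUE
  else if (cfg$admission_strict) state$next_id < extreme
  else state$next_id <= extreme
  state$admission_log[[length(state$admission_log) + 1L]] <-
    list(frame = state$frame_count, candidate_id = state$next_id,
         extreme = extreme, gate_active = gate_active, created = admit)
  if (admit) {
    tr <- new_track(state$next_id, det_box, embedding, conf, cfg)
    state$tracks[[length(state$tracks) + 1L]] <- tr
    state$next_id <- state$next_id + 1L
  }
  list(state = state, created = admit)
}

#' Appearance cascade matching over confirmed tracks
#'
#' Iterates time-since-update levels 1..`max_age`; at each level solves
#' a min-cost assignment on the gallery cosine cost, with pairs whose
#' squared Mahalanobis distance exceeds the gating threshold, or whose
#' cosine cost exceeds `max_cosine_distance`, marked infeasible.
#' Recently seen tracks therefore get priority over long-missed ones.
#'
#' @param tracks list of confirmed tracks (post-prediction).
#' @param det_boxes detection boxes, tlwh matrix.
#' @param det_emb detection embedding matrix (one row per detection);
#'   required.
#' @param cfg a [tracker_config()].
#' @return `list(matches, unmatched_tracks, unmatched_dets)`, matches a
#'   two-column matrix of (track index, detection index).
#' @export
cascade_match <- function(tracks, det_boxes, det_emb, cfg = tracker_config()) {
  n_det <- if (is.null(det_boxes)) 0L else nrow(as_box_matrix(det_boxes))
  res <- list(matches = matrix(integer(0), ncol = 2L),
              unmatched_tracks = seq_along(tracks),
              unmatched_dets = seq_len(n_det))
  if (!length(tracks) || n_det == 0L) return(res)
  if (is.null(det_emb)) stop("cascade matching requires detection embeddings")
  det_emb <- as.matrix(det_emb)
  det_xyah <- tlwh_to_xyah(as_box_matrix(det_boxes))
  if (is.null(dim(det_xyah))) det_xyah <- matrix(det_xyah, nrow = 1L)
  free_dets <- seq_len(n_det)
  matches <- NULL
  tsu <- vapply(tracks, function(t) t$time_since_update, 0L)
  for (level in sort(unique(tsu))) {
    if (!length(free_dets)) break
    if (level > cfg$max_age) break
    idx <- which(tsu == level)
    cost <- matrix(Inf, length(idx), length(free_dets))
    for (k in seq_along(idx)) {
      tr <- tracks[[idx[k]]]
      appearance <- gallery_cost_matrix(tr$gallery,
                                        det_emb[free_dets, , drop = FALSE])
      gd <- kf_gating_distance(tr$kf, det_xyah[free_dets, , drop = FALSE])
      appearance[gd > cfg$gating_threshold] <- Inf
      appearance[appearance > cfg$max_cosine_distance] <- Inf
      cost[k, ] <- appearance
    }
    sol <- solve_assignment(cost, gate = cfg$max_cosine_distance)
    if (nrow(sol$matches)) {
      matches <- rbind(matches,
                       cbind(idx[sol$matches[, 1L]],
                             free_dets[sol$matches[, 2L]]))
      free_dets <- free_dets[-sol$matches[, 2L]]
    }
  }
  if (!is.null(matches)) {
    res$matches <- matches
    res$unmatched_tracks <- setdiff(seq_along(tracks), matches[, 1L])
    res$unmatched_dets <- free_dets
  }
  res
}

#' IOU matching of tracks to detections
#'
#' One min-cost assignment on `1 - IoU` between predicted track boxes
#' and detection boxes under a cost gate.  The same operation serves
#' the primary pass (default gate) and the secondary, relaxed pass.
#'
#' @param tracks list of tracks (post-prediction).
#' @param det_boxes detection boxes, tlwh matrix.
#' @param gate maximum admissible cost (default 0.7).
#' @return `list(matches, unmatched_tracks, unmatched_dets)`.
#' @export
iou_match <- function(tracks, det_boxes, gate = 0.7) {
  n_det <- if (is.null(det_boxes)) 0L else nrow(as_box_matrix(det_boxes))
  if (!length(tracks) || n_det == 0L) {
    return(list(matches = matrix(integer(0), ncol = 2L),
                unmatched_tracks = seq_along(tracks),
                unmatched_dets = seq_len(n_det)))
  }
  tboxes <- do.call(rbind, lapply(tracks, track_tlwh))
  sol <- solve_assignment(iou_cost_matrix(tboxes, det_boxes), gate = gate)
  list(matches = unname(sol$matches),
       unmatched_tracks = sol$unmatched_rows,
       unmatched_dets = sol$unmatched_cols)
}

#' Advance the tracker by one frame
#'
#' Runs the full per-frame pipeline: confidence filtering, Kalman
#' prediction, cascade matching of confirmed tracks, primary IOU
#' matching of tentative tracks plus just-missed confirmed tracks,
#' the secondary relaxed-IOU pass over the stage-2 leftovers, track
#' updates and lifecycle transitions, admission-gated creation of new
#' tracks from unmatched detections, and the push of the current
#' maximum live id into the ring buffer.
#'
#' @param state a `tracker_state`.
#' @param det_boxes detection boxes for this frame (tlwh matrix, may be
#'   NULL/empty).
#' @param det_conf detection confidences (default 1).
#' @param det_emb optional embedding matrix aligned with `det_boxes`.
#' @param frame frame number; must exceed the last processed frame.
#' @return `list(state, output)`; `output` is a data.frame of emitted
#'   (confirmed, just-updated) tracks: `frame, id, l, t, w, h, conf`.
#' @export
tracker_step <- function(state, det_boxes = NULL, det_conf = NULL,
                         det_emb = NULL, frame = state$frame_count + 1L) {
  cfg <- state$config
  if (frame <= state$frame_count)
    stop("frames must be presented in increasing order")
  state$frame_count <- as.integer(frame)

  n_det <- if (is.null(det_boxes)) 0L else nrow(as_box_matrix(det_boxes))
  if (n_det) {
    det_boxes <- as_box_matrix(det_boxes)
    if (is.null(det_conf)) det_conf <- rep(1, n_det)
    keep <- which(det_conf >= cfg$min_confidence)
    det_boxes <- det_boxes[keep, , drop = FALSE]
    det_conf <- det_conf[keep]
    if (!is.null(det_emb))
      det_emb <- l2_normalize(as.matrix(det_emb)[keep, , drop = FALSE])
    n_det <- length(keep)
  }

  # predict all live tracks
  state$tracks <- lapply(state$tracks, function(tr) {
    tr$kf <- kf_predict(tr$kf)
    tr$age <- tr$age + 1L
    tr$time_since_update <- tr$time_since_update + 1L
    tr
  })

  status <- vapply(state$tracks, function(t) t$status, "")
  confirmed <- which(status == "confirmed")
  tentative <- which(status == "tentative")

  matches <- NULL    # (track index, det index)

  # stage 1: appearance cascade over confirmed tracks
  cas_unmatched <- confirmed
  free_dets <- seq_len(n_det)
  if (length(confirmed) && n_det) {
    cas <- cascade_match(state$tracks[confirmed], det_boxes, det_emb, cfg)
    if (nrow(cas$matches))
      matches <- cbind(confirmed[cas$matches[, 1L]], cas$matches[, 2L])
    cas_unmatched <- confirmed[cas$unmatched_tracks]
    free_dets <- cas$unmatched_dets
  }

  # stage 2: primary IOU over tentative + just-missed confirmed tracks
  iou_cand <- c(tentative,
                cas_unmatched[vapply(state$tracks[cas_unmatched],
                                     function(t) t$time_since_update,
                                     0L) == 1L])
  iou_cand <- sort(iou_cand)
  leftover_tracks <- setdiff(cas_unmatched, iou_cand)
  if (length(iou_cand) && length(free_dets)) {
    pri <- iou_match(state$tracks[iou_cand],
                     det_boxes[free_dets, , drop = FALSE],
                     gate = cfg$primary_iou_gate)
    if (nrow(pri$matches))
      matches <- rbind(matches, cbind(iou_cand[pri$matches[, 1L]],
                                      free_dets[pri$matches[, 2L]]))
    sec_tracks <- iou_cand[pri$unmatched_tracks]
    free_dets <- free_dets[pri$unmatched_dets]
  } else {
    sec_tracks <- iou_cand
  }

  # stage 3: secondary IOU at the relaxed gate
  if (cfg$secondary_scope == "all_unmatched")
    sec_tracks <- sort(c(sec_tracks, leftover_tracks))
  if (cfg$secondary_iou_enabled && length(sec_tracks) && length(free_dets)) {
    sec <- iou_match(state$tracks[sec_tracks],
                     det_boxes[free_dets, , drop = FALSE],
                     gate = cfg$secondary_iou_gate)
    if (nrow(sec$matches))
      matches <- rbind(matches, cbind(sec_tracks[sec$matches[, 1L]],
                                      free_dets[sec$matches[, 2L]]))
    free_dets <- free_dets[sec$unmatched_dets]
  }

  # apply updates to matched tracks
  if (!is.null(matches) && nrow(matches)) {
    for (k in seq_len(nrow(matches))) {
      ti <- matches[k, 1L]; di <- matches[k, 2L]
      tr <- state$tracks[[ti]]
      tr$kf <- kf_update(tr$kf, tlwh_to_xyah(det_boxes[di, ]))
      if (!is.null(det_emb))
        tr$gallery <- gallery_append(tr$gallery, det_emb[di, ],
                                     cfg$gallery_budget)
      tr$hits <- tr$hits + 1L
      tr$time_since_update <- 0L
      tr$conf <- det_conf[di]
      if (tr$status == "tentative" && tr$hits >= cfg$n_init)
        tr$status <- "confirmed"
      state$tracks[[ti]] <- tr
    }
  }

  # lifecycle of unmatched tracks
  matched_idx <- if (is.null(matches)) integer(0) else matches[, 1L]
  for (ti in setdiff(seq_along(state$tracks), matched_idx)) {
    tr <- state$tracks[[ti]]
    if (tr$status == "tentative") {
      tr$status <- "deleted"
    } else if (tr$status == "confirmed" &&
               tr$time_since_update > cfg$max_age) {
      tr$status <- "deleted"
    }
    state$tracks[[ti]] <- tr
  }

  # admit new tracks from unmatched detections, in file order
  for (di in free_dets) {
    adm <- admit_new_track(state, det_boxes[di, ],
                           embedding = if (is.null(det_emb)) NULL else
                             det_emb[di, ],
                           conf = det_conf[di])
    state <- adm$state
  }

  # drop deleted tracks, push the per-frame max live id
  state$tracks <- Filter(function(t) t$status != "deleted", state$tracks)
  live_ids <- vapply(state$tracks, function(t) t$id, 0L)
  state$max_id_history <- c(state$max_id_history,
                            if (length(live_ids)) max(live_ids) else 0L)
  w <- cfg$extreme_id_window
  if (length(state$max_id_history) > w)
    state$max_id_history <-
      state$max_id_history[(length(state$max_id_history) - w + 1L):
                             length(state$max_id_history)]

  emit <- Filter(function(t) {
    t$time_since_update == 0L &&
      (t$status == "confirmed" || (cfg$emit_tentative && t$status == "tentative"))
  }, state$tracks)
  emit <- emit[order(vapply(emit, function(t) t$id, 0L))]
  output <- if (length(emit)) {
    boxes <- do.call(rbind, lapply(emit, track_tlwh))
    data.frame(frame = frame,
               id = vapply(emit, function(t) t$id, 0L),
               l = boxes[, 1L], t = boxes[, 2L],
               w = boxes[, 3L], h = boxes[, 4L],
               conf = vapply(emit, function(t) t$conf, 0))
  } else {
    data.frame(frame = integer(0), id = integer(0), l = numeric(0),
               t = numeric(0), w = numeric(0), h = numeric(0),
               conf = numeric(0))
  }
  list(state = state, output = output)
}

#' Track a whole detection sequence
#'
#' Iterates [tracker_step()] over frames `1..n_frames`, feeding each
#' frame's detections (and sidecar embeddings, row-aligned with the
#' detection table) in file order.
#'
#' @param detections data.frame with columns `frame, l, t, w, h, conf`
#'   (as from [read_mot()] with `kind = "det"`).
#' @param embeddings optional numeric matrix, one row per detection row.
#' @param config a [tracker_config()].
#' @param n_frames number of frames to process (default: max frame seen).
#' @param return_state also return the final `tracker_state`
#'   (default FALSE).
#' @return A data.frame of emitted track boxes `frame, id, l, t, w, h,
#'   conf`, or `list(result, state)` when `return_state` is TRUE.
#' @export
track_sequence <- function(detections, embeddings = NULL,
                           config = tracker_config(),
                           n_frames = NULL, return_state = FALSE) {
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (nrow(embeddings) != nrow(detections))
      stop("embeddings must have one row per detection")
  }
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) else 0L
  state <- tracker_create(config)
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    rows <- by_frame[[as.character(f)]]
    if (length(rows)) {
      step <- tracker_step(state,
                           det_boxes = as.matrix(detections[rows, c("l", "t", "w", "h")]),
                           det_conf = detections$conf[rows],
                           det_emb = if (is.null(embeddings)) NULL else
                             embeddings[rows, , drop = FALSE],
                           frame = f)
    } else {
      step <- tracker_step(state, NULL, frame = f)
    }
    state <- step$state
    out[[f]] <- step$output
  }
  result <- do.call(rbind, out)
  if (is.null(result))
    result <- data.frame(frame = integer(0), id = integer(0), l = numeric(0),
                         t = numeric(0), w = numeric(0), h = numeric(0),
                         conf = numeric(0))
  rownames(result) <- NULL
  if (return_state) list(result = result, state = state) else result
}

#' Admission log of a tracker run
#'
#' One row per new-track decision: the frame, the candidate id, the
#' extreme ID value at that moment, whether the gate was active, and
#' whether a track was created.
#'
#' @param state a `tracker_state` (e.g. from
#'   `track_sequence(..., return_state = TRUE)`).
#' @return A data.frame (0-row if no decisions were taken).
#' @export
admission_log <- function(state) {
  if (!length(state$admission_log)) {
    return(data.frame(frame = integer(0), candidate_id = integer(0),
                      extreme = integer(0), gate_active = logical(0),
                      created = logical(0)))
  }
  do.call(rbind, lapply(state$admission_log, function(e) {
    data.frame(frame = e$frame, candidate_id = e$candidate_id,
               extreme = if (is.na(e$extreme)) NA_integer_ else e$extreme,
               gate_active = e$gate_active, created = e$created)
  }))
}
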