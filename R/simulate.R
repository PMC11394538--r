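#' Synthetic herd simulator
#'
#' Generates desk-scale stand-ins for overhead pen video of a fixed
#' herd: every animal is present in every frame (enclosed pen), moves
#' as a bounded random walk with reflecting walls, and occasionally
#' enters a scheduled pairwise occlusion burst (two animals steered
#' together until their boxes overlap at IoU >= 0.5, held for a fixed
#' duration, then released) emulating fighting/mounting clusters.
#' Detector noise is applied on top of the ground truth: occlusion-
#' dependent missed detections, Gaussian bounding-box jitter,
#' Poisson-distributed false-positive boxes, and confidence degraded
#' with jitter magnitude.  Appearance embeddings are identity-anchored
#' unit vectors with noise that grows during occlusion; false positives
#' draw embeddings from fresh, never-reused identities.  The whole
#' sequence is a pure function of its configuration, seed included.
#'
#' @name simulate
NULL

#' Scenario configuration for the herd simulator
#'
#' @param n_animals herd size (>= 1).
#' @param arena pen size in pixels, `c(width, height)`.
#' @param n_frames sequence length in frames.
#' @param box_size mean and sd of animal box width in pixels.
#' @param speed_sd random-walk step sd, pixels/frame.
#' @param occlusion_event_rate expected occlusion events per frame.
#' @param occlusion_duration hold length of an occlusion burst, frames.
#' @param miss_prob_base detector miss probability in the open.
#' @param miss_prob_occluded miss probability during occlusion
#'   (>= `miss_prob_base`).
#' @param fp_rate expected false-positive boxes per frame (Poisson).
#' @param jitter_sd Gaussian sd added to each box parameter, pixels.
#' @param embed_noise_sd embedding noise sd in the open.
#' @param embed_noise_occluded_sd embedding noise sd during occlusion.
#' @param seed RNG seed; the sequence is bit-reproducible given the
#'   full configuration.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_animals = 4L,
                            arena = c(1920, 1080),
                            n_frames = 500L,
                            box_size = c(200, 15),
                            speed_sd = 3,
                            occlusion_event_rate = 0.005,
                            occlusion_duration = 10L,
                            miss_prob_base = 0.02,
                            miss_prob_occluded = 0.3,
                            fp_rate = 0.02,
                            jitter_sd = 1.5,
                            embed_noise_sd = 0.02,
                            embed_noise_occluded_sd = 0.08,
                            seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals), arena = as.numeric(arena),
              n_frames = as.integer(n_frames), box_size = as.numeric(box_size),
              speed_sd = speed_sd,
              occlusion_event_rate = occlusion_event_rate,
              occlusion_duration = as.integer(occlusion_duration),
              miss_prob_base = miss_prob_base,
              miss_prob_occluded = miss_prob_occluded,
              fp_rate = fp_rate, jitter_sd = jitter_sd,
              embed_noise_sd = embed_noise_sd,
              embed_noise_occluded_sd = embed_noise_occluded_sd,
              seed = as.integer(seed))
  if (cfg$n_animals < 1L) stop("n_animals must be >= 1")
  probs <- c(cfg$miss_prob_base, cfg$miss_prob_occluded)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$miss_prob_occluded < cfg$miss_prob_base)
    stop("miss_prob_occluded must be >= miss_prob_base")
  if (cfg$n_animals * (cfg$box_size[1L] + 4 * cfg$box_size[2L])^2 * 2 >
      prod(cfg$arena))
    stop("arena too small for ", cfg$n_animals, " animals of this box size")
  class(cfg) <- "scenario_config"
  cfg
}

#' Named scenario presets
#'
#' `"sparse"`: a lightly stocked pen of 4 animals with large boxes and
#' rare contact events.  `"distant_dense"`: a far-camera view of a
#' densely stocked pen of 7 animals with small boxes, frequent
#' occlusion bursts, heavy occlusion-driven detector misses, frequent
#' false positives and unreliable appearance features during contact.
#'
#' @param name `"sparse"` or `"distant_dense"`.
#' @param ... overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name = c("sparse", "distant_dense"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    sparse = list(n_animals = 4L, arena = c(1920, 1080), n_frames = 500L,
                  box_size = c(200, 15), speed_sd = 3,
                  occlusion_event_rate = 0.005, occlusion_duration = 10L,
                  miss_prob_base = 0.02, miss_prob_occluded = 0.3,
                  fp_rate = 0.02, jitter_sd = 1.5,
                  embed_noise_sd = 0.02, embed_noise_occluded_sd = 0.08),
    distant_dense = list(n_animals = 7L, arena = c(1280, 720),
                         n_frames = 600L, box_size = c(80, 8), speed_sd = 2,
                         occlusion_event_rate = 0.04,
                         occlusion_duration = 15L,
                         miss_prob_base = 0.05, miss_prob_occluded = 0.55,
                         fp_rate = 0.15, jitter_sd = 2,
                         embed_noise_sd = 0.025,
                         embed_noise_occluded_sd = 0.12))
  over <- list(...)
  base[names(over)] <- over
  do.call(scenario_config, base)
}

#' Generate ground-truth trajectories and the occlusion log
#'
#' Uses the current RNG stream; seed it (or call via
#' [simulate_sequence()]) for reproducibility.
#'
#' @param cfg a [scenario_config()].
#' @return A list: `gt` data.frame (`frame, id, l, t, w, h`), and
#'   `occlusions` data.frame of logged intervals (`id_a, id_b, start,
#'   end`) during which the pair's boxes overlap at IoU >= 0.5.
#' @export
generate_truth <- function(cfg) {
  n <- cfg$n_animals
  W <- cfg$arena[1L]; H <- cfg$arena[2L]
  w <- pmin(pmax(stats::rnorm(n, cfg$box_size[1L], cfg$box_size[2L]),
                 cfg$box_size[1L] - 2 * cfg$box_size[2L]),
            cfg$box_size[1L] + 2 * cfg$box_size[2L])
  w <- pmax(w, 8)
  aspect <- stats::runif(n, 1.2, 1.8)
  h <- w / aspect
  cx <- stats::runif(n, w / 2, W - w / 2)
  cy <- stats::runif(n, h / 2, H - h / 2)

  # active occlusion events: list(a, b, phase, frames_left, start).
  # The pursuer closes in at a capped "chase" speed (a brisk walk,
  # 2.5x the walk sd) so ground-truth motion stays plausible; after
  # an event both animals are refractory (disengaged) for twice the
  # hold duration before they can be scheduled again.
  chase_speed <- 2.5 * cfg$speed_sd
  events <- list()
  busy <- logical(n)
  refractory <- integer(n)
  occ_log <- NULL
  gt <- vector("list", cfg$n_frames)
  occ_flags <- matrix(FALSE, cfg$n_frames, n)

  pair_iou <- function(i, j) {
    box_iou(c(cx[i] - w[i] / 2, cy[i] - h[i] / 2, w[i], h[i]),
            c(cx[j] - w[j] / 2, cy[j] - h[j] / 2, w[j], h[j]))
  }

  for (f in seq_len(cfg$n_frames)) {
    refractory <- pmax(refractory - 1L, 0L)
    # schedule a new occlusion event between the two closest free animals
    free_now <- which(!busy & refractory == 0L)
    if (stats::runif(1) < cfg$occlusion_event_rate && length(free_now) >= 2L) {
      d2 <- outer(cx[free_now], cx[free_now], `-`)^2 +
        outer(cy[free_now], cy[free_now], `-`)^2
      diag(d2) <- Inf
      k <- arrayInd(which.min(d2), dim(d2))
      pair <- free_now[as.vector(k)]
      events[[length(events) + 1L]] <-
        list(a = pair[1L], b = pair[2L], phase = "approach",
             frames_left = 0L, start = NA_integer_, stuck = 0L)
      busy[pair] <- TRUE
    }
    steered <- logical(n)
    drop <- integer(0)
    for (k in seq_along(events)) {
      ev <- events[[k]]
      if (ev$phase == "approach") {
        dx <- cx[ev$a] - cx[ev$b]; dy <- cy[ev$a] - cy[ev$b]
        gap <- sqrt(dx^2 + dy^2)
        step_len <- min(0.35 * gap, chase_speed)
        if (gap > 0) {
          cx[ev$b] <- cx[ev$b] + step_len * dx / gap
          cy[ev$b] <- cy[ev$b] + step_len * dy / gap
        }
        steered[ev$b] <- TRUE
        ev$stuck <- ev$stuck + 1L
        if (pair_iou(ev$a, ev$b) >= 0.5) {
          ev$phase <- "hold"
          ev$frames_left <- cfg$occlusion_duration
          ev$start <- f
          steered[ev$a] <- TRUE   # the target freezes once contact begins
        } else if ((gap < 1 && pair_iou(ev$a, ev$b) < 0.5) ||
                   ev$stuck > 150L) {
          # geometry cannot reach the overlap threshold; abandon unlogged
          busy[c(ev$a, ev$b)] <- FALSE
          refractory[c(ev$a, ev$b)] <- 2L * cfg$occlusion_duration
          drop <- c(drop, k)
        }
      } else {
        # close the residual offset smoothly at chase speed (the mover
        # climbs on, it does not teleport to the target centre)
        tx <- cx[ev$a] + 0.05 * w[ev$a]; ty <- cy[ev$a] + 0.05 * h[ev$a]
        dx <- tx - cx[ev$b]; dy <- ty - cy[ev$b]
        gap <- sqrt(dx^2 + dy^2)
        if (gap > 0) {
          step_len <- min(gap, chase_speed)
          cx[ev$b] <- cx[ev$b] + step_len * dx / gap
          cy[ev$b] <- cy[ev$b] + step_len * dy / gap
        }
        steered[ev$b] <- TRUE
        steered[ev$a] <- TRUE   # pinned under the mover
        # the stationary target underneath is the one the detector
        # loses; the mover stays visible on top
        occ_flags[f, ev$a] <- TRUE
        ev$frames_left <- ev$frames_left - 1L
        if (ev$frames_left <= 0L) {
          occ_log <- rbind(occ_log,
                           data.frame(id_a = ev$a, id_b = ev$b,
                                      start = ev$start, end = f))
          busy[c(ev$a, ev$b)] <- FALSE
          refractory[c(ev$a, ev$b)] <- 2L * cfg$occlusion_duration
          drop <- c(drop, k)
        }
      }
      events[[k]] <- ev
    }
    if (length(drop)) events <- events[-drop]

    # random walk with reflecting walls for unsteered animals
    free <- which(!steered)
    if (length(free)) {
      cx[free] <- cx[free] + stats::rnorm(length(free), 0, cfg$speed_sd)
      cy[free] <- cy[free] + stats::rnorm(length(free), 0, cfg$speed_sd)
    }
    cx <- reflect(cx, w / 2, W - w / 2)
    cy <- reflect(cy, h / 2, H - h / 2)

    gt[[f]] <- data.frame(frame = f, id = seq_len(n),
                          l = cx - w / 2, t = cy - h / 2, w = w, h = h)
  }
  gt <- do.call(rbind, gt)
  rownames(gt) <- NULL
  if (is.null(occ_log))
    occ_log <- data.frame(id_a = integer(0), id_b = integer(0),
                          start = integer(0), end = integer(0))
  list(gt = gt, occlusions = occ_log, occluded = occ_flags)
}

reflect <- function(x, lo, hi) {
  bad <- hi <= lo
  x <- ifelse(bad, (lo + hi) / 2, x)   # degenerate range: pin to centre
  x <- ifelse(x < lo, 2 * lo - x, x)
  x <- ifelse(x > hi, 2 * hi - x, x)
  pmin(pmax(x, lo), hi)
}

occluded_at <- function(truth, frame, id) {
  if (!is.null(truth$occluded)) return(truth$occluded[frame, id])
  any(truth$occlusions$start <= frame & truth$occlusions$end >= frame &
        (truth$occlusions$id_a == id | truth$occlusions$id_b == id))
}

#' Degrade ground truth into detector output
#'
#' Each ground-truth box is dropped with the base miss probability (or
#' the occluded one inside logged occlusion intervals); survivors get
#' Gaussian jitter on all four box parameters; Poisson false positives
#' are placed uniformly with random sizes.  Confidence is
#' `1 - |jitter| / box diagonal`, clipped to `[0.5, 1]`.
#'
#' @param truth output of [generate_truth()].
#' @param cfg the [scenario_config()].
#' @return A data.frame of detections `frame, l, t, w, h, conf` plus
#'   truth annotations `src_id` (NA for false positives) and
#'   `occluded`.
#' @export
apply_detector_noise <- function(truth, cfg) {
  gt <- truth$gt
  n <- nrow(gt)
  occ <- if (n) mapply(function(f, i) occluded_at(truth, f, i),
                       gt$frame, gt$id) else logical(0)
  miss_p <- ifelse(occ, cfg$miss_prob_occluded, cfg$miss_prob_base)
  kept <- stats::runif(n) >= miss_p
  out <- NULL
  if (any(kept)) {
    g <- gt[kept, , drop = FALSE]
    delta <- matrix(stats::rnorm(4L * nrow(g), 0, cfg$jitter_sd),
                    ncol = 4L)
    l <- g$l + delta[, 1L]; t <- g$t + delta[, 2L]
    w <- pmax(g$w + delta[, 3L], 4); h <- pmax(g$h + delta[, 4L], 4)
    jn <- sqrt(rowSums(delta^2)) / sqrt(g$w^2 + g$h^2)
    conf <- pmin(pmax(1 - jn, 0.5), 1)
    out <- data.frame(frame = g$frame, l = l, t = t, w = w, h = h,
                      conf = conf, src_id = g$id, occluded = occ[kept])
  }
  # false positives
  W <- cfg$arena[1L]; H <- cfg$arena[2L]
  for (f in seq_len(cfg$n_frames)) {
    k <- stats::rpois(1L, cfg$fp_rate)
    if (k == 0L) next
    w <- stats::runif(k, 0.5, 1.5) * cfg$box_size[1L]
    h <- w / stats::runif(k, 1.2, 1.8)
    l <- stats::runif(k, 0, pmax(W - w, 1))
    t <- stats::runif(k, 0, pmax(H - h, 1))
    out <- rbind(out, data.frame(frame = f, l = l, t = t, w = w, h = h,
                                 conf = stats::runif(k, 0.5, 1),
                                 src_id = NA_integer_, occluded = FALSE))
  }
  if (is.null(out))
    out <- data.frame(frame = integer(0), l = numeric(0), t = numeric(0),
                      w = numeric(0), h = numeric(0), conf = numeric(0),
                      src_id = integer(0), occluded = logical(0))
  key <- ifelse(is.na(out$src_id), .Machine$integer.max, out$src_id)
  out <- out[order(out$frame, key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach appearance embeddings to detections
#'
#' True detections get the identity's anchored embedding with the open
#' or occluded noise level; false positives draw from fresh identities
#' never assigned to an animal.
#'
#' @param detections output of [apply_detector_noise()].
#' @param cfg the [scenario_config()].
#' @param dim embedding dimension (default 256).
#' @return A numeric matrix, one unit-norm row per detection.
#' @export
sample_embeddings <- function(detections, cfg, dim = EMBED_DIM) {
  n <- nrow(detections)
  emb <- matrix(0, n, dim)
  fp_next <- cfg$n_animals
  for (k in seq_len(n)) {
    if (is.na(detections$src_id[k])) {
      fp_next <- fp_next + 1L
      emb[k, ] <- mock_embed(fp_next, cfg$embed_noise_sd, dim)
    } else {
      sigma <- if (detections$occluded[k]) cfg$embed_noise_occluded_sd
      else cfg$embed_noise_sd
      emb[k, ] <- mock_embed(detections$src_id[k], sigma, dim)
    }
  }
  emb
}

#' Simulate a complete synthetic sequence
#'
#' Seeds the RNG from the configuration and runs truth generation,
#' detector-noise application, and embedding sampling.
#'
#' @param cfg a [scenario_config()] or [scenario_preset()].
#' @param dim embedding dimension (default 256).
#' @return A list: `gt`, `detections`, `embeddings`, `occlusions`,
#'   `config`.
#' @export
simulate_sequence <- function(cfg, dim = EMBED_DIM) {
  set.seed(cfg$seed)
  truth <- generate_truth(cfg)
  dets <- apply_detector_noise(truth, cfg)
  emb <- sample_embeddings(dets, cfg, dim)
  list(gt = truth$gt, detections = dets, embeddings = emb,
       occlusions = truth$occlusions, config = cfg)
}

#' Write a simulated sequence to MOT-16 files
#'
#' Writes `gt.txt`, `det.txt`, `features.txt` (sidecar) and
#' `truth_log.txt` (key-value occlusion intervals) under `dir`; every
#' file carries the seed as a comment header.
#'
#' @param sim output of [simulate_sequence()].
#' @param dir output directory (created).
#' @return Invisibly, the named vector of file paths.
#' @export
write_sequence <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("seed=", sim$config$seed)
  paths <- c(gt = file.path(dir, "gt.txt"),
             det = file.path(dir, "det.txt"),
             features = file.path(dir, "features.txt"),
             truth_log = file.path(dir, "truth_log.txt"))
  gt <- sim$gt
  gt$conf <- 1
  write_mot(gt, paths[["gt"]], header = hdr)
  det <- sim$detections
  det$id <- -1L
  write_mot(det, paths[["det"]], header = hdr)
  write_feature_sidecar(sim$embeddings, paths[["features"]], header = hdr)
  occ <- sim$occlusions
  writeLines(c(paste0("# ", hdr),
               sprintf("occlusion id_a=%d id_b=%d start=%d end=%d",
                       occ$id_a, occ$id_b, occ$start, occ$end)),
             paths[["truth_log"]])
  invisible(paths)
}
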