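# Independent oracles used to validate the package implementations.
# Each is written from first principles (enumeration, closed forms, or
# textbook formulas) and never calls the code path it checks.

# IoU by counting sub-pixel grid cells.
grid_iou <- function(b1, b2, res = 0.1) {
  xs <- seq(min(b1[1], b2[1]), max(b1[1] + b1[3], b2[1] + b2[3]), by = res)
  ys <- seq(min(b1[2], b2[2]), max(b1[2] + b1[4], b2[2] + b2[4]), by = res)
  cx <- xs[-length(xs)] + res / 2
  cy <- ys[-length(ys)] + res / 2
  inside <- function(b, px, py) {
    outer(px, py, function(x, y)
      x > b[1] & x < b[1] + b[3] & y > b[2] & y < b[2] + b[4])
  }
  i1 <- inside(b1, cx, cy); i2 <- inside(b2, cx, cy)
  sum(i1 & i2) / sum(i1 | i2)
}

# Exhaustive minimum-cost assignment: tries every injection of the
# smaller dimension into the larger.
brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(list(cost = 0, pairs = NULL))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf; best_pairs <- NULL
  if (n <= m) {
    for (cols in utils::combn(m, n, simplify = FALSE)) {
      for (p in perms(cols)) {
        tot <- sum(cost[cbind(seq_len(n), p)])
        if (tot < best) { best <- tot; best_pairs <- cbind(seq_len(n), p) }
      }
    }
  } else {
    sub <- brute_assignment(t(cost))
    best <- sub$cost
    best_pairs <- sub$pairs[, 2:1, drop = FALSE]
  }
  list(cost = best, pairs = best_pairs)
}

# Textbook Kalman filter over the box state, written independently with
# explicit measurement matrices and solve().
ref_kf <- local({
  H <- cbind(diag(4), matrix(0, 4, 4))
  Fm <- diag(8); Fm[1, 5] <- Fm[2, 6] <- Fm[3, 7] <- Fm[4, 8] <- 1
  list(
    init = function(z, wp = 1 / 20, wv = 1 / 160) {
      h <- z[4]
      sd <- c(2 * wp * h, 2 * wp * h, 1e-2, 2 * wp * h,
              10 * wv * h, 10 * wv * h, 1e-5, 10 * wv * h)
      list(x = c(z, rep(0, 4)), P = diag(sd^2), wp = wp, wv = wv)
    },
    predict = function(s) {
      h <- s$x[4]
      q <- c(s$wp * h, s$wp * h, 1e-2, s$wp * h,
             s$wv * h, s$wv * h, 1e-5, s$wv * h)
      list(x = as.numeric(Fm %*% s$x),
           P = Fm %*% s$P %*% t(Fm) + diag(q^2), wp = s$wp, wv = s$wv)
    },
    update = function(s, z) {
      h <- s$x[4]
      r <- c(s$wp * h, s$wp * h, 1e-1, s$wp * h)
      S <- H %*% s$P %*% t(H) + diag(r^2)
      K <- s$P %*% t(H) %*% solve(S)
      x <- s$x + as.numeric(K %*% (z - H %*% s$x))
      P <- (diag(8) - K %*% H) %*% s$P
      list(x = x, P = P, wp = s$wp, wv = s$wv)
    },
    gating = function(s, z) {
      h <- s$x[4]
      r <- c(s$wp * h, s$wp * h, 1e-1, s$wp * h)
      S <- H %*% s$P %*% t(H) + diag(r^2)
      d <- z - as.numeric(H %*% s$x)
      as.numeric(t(d) %*% solve(S) %*% d)
    })
})

# Brute-force CLEAR-MOT evaluation for tiny instances: per frame,
# carry-over then exhaustive search over injective gt->hyp mappings
# maximising total IoU subject to the threshold; identity metrics via
# exhaustive search over all partial id bijections.
oracle_clearmot <- function(gt, hyp, thr = 0.5) {
  frames <- sort(union(gt$frame, hyp$frame))
  last <- list()
  GT <- 0; FP <- 0; FN <- 0; IDS <- 0; iou_sum <- 0; nmatch <- 0
  total_hyp <- 0
  overlap <- list()
  injections <- function(gs, hs) {
    # all mappings of a subset of gs into distinct hs (indices)
    res <- list(list())
    for (g in gs) {
      new <- list()
      for (m in res) {
        new[[length(new) + 1]] <- m           # g unmatched
        used <- unlist(m)
        for (h in setdiff(hs, used)) {
          m2 <- m; m2[[as.character(g)]] <- h
          new[[length(new) + 1]] <- m2
        }
      }
      res <- new
    }
    res
  }
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- hyp[hyp$frame == f, , drop = FALSE]
    GT <- GT + nrow(g); total_hyp <- total_hyp + nrow(h)
    iou <- if (nrow(g) && nrow(h))
      box_iou_matrix(as.matrix(g[, c("l", "t", "w", "h")]),
                     as.matrix(h[, c("l", "t", "w", "h")]))
    else matrix(0, nrow(g), nrow(h))
    taken_g <- integer(0); taken_h <- integer(0); pairs <- NULL
    for (gi in seq_len(nrow(g))) {
      ph <- last[[as.character(g$id[gi])]]
      if (is.null(ph)) next
      hi <- match(ph, h$id)
      if (is.na(hi) || hi %in% taken_h) next
      if (iou[gi, hi] >= thr) {
        pairs <- rbind(pairs, c(gi, hi))
        taken_g <- c(taken_g, gi); taken_h <- c(taken_h, hi)
      }
    }
    rem_g <- setdiff(seq_len(nrow(g)), taken_g)
    rem_h <- setdiff(seq_len(nrow(h)), taken_h)
    best <- NULL; best_iou <- -1
    for (m in injections(rem_g, rem_h)) {
      ok <- all(vapply(names(m), function(gi)
        iou[as.integer(gi), m[[gi]]] >= thr, TRUE))
      if (!ok) next
      tot <- sum(vapply(names(m), function(gi)
        iou[as.integer(gi), m[[gi]]], 0))
      if (length(m) > length(best) ||
          (length(m) == length(best) && tot > best_iou)) {
        best <- m; best_iou <- tot
      }
    }
    for (gi in names(best)) pairs <- rbind(pairs, c(as.integer(gi), best[[gi]]))
    nm <- if (is.null(pairs)) 0 else nrow(pairs)
    FN <- FN + nrow(g) - nm
    FP <- FP + nrow(h) - nm
    nmatch <- nmatch + nm
    if (nm) for (k in seq_len(nm)) {
      gi <- pairs[k, 1]; hi <- pairs[k, 2]
      gid <- g$id[gi]; hid <- h$id[hi]
      iou_sum <- iou_sum + iou[gi, hi]
      prev <- last[[as.character(gid)]]
      if (!is.null(prev) && prev != hid) IDS <- IDS + 1
      last[[as.character(gid)]] <- hid
      key <- paste(gid, hid)
      overlap[[key]] <- (if (is.null(overlap[[key]])) 0 else overlap[[key]]) + 1
    }
  }
  # IDF1 by exhaustive bijection search
  keys <- names(overlap) %||% character(0)
  gids <- unique(vapply(strsplit(keys, " "), `[`, "", 1))
  hids <- unique(vapply(strsplit(keys, " "), `[`, "", 2))
  ov <- function(g, h) {
    v <- overlap[[paste(g, h)]]
    if (is.null(v)) 0 else v
  }
  best_idtp <- 0
  maps <- list(list())
  for (g in gids) {
    new <- list()
    for (m in maps) {
      new[[length(new) + 1]] <- m
      for (h in setdiff(hids, unlist(m)))
        { m2 <- m; m2[[g]] <- h; new[[length(new) + 1]] <- m2 }
    }
    maps <- new
  }
  for (m in maps) {
    tot <- sum(vapply(names(m), function(g) ov(g, m[[g]]), 0))
    if (tot > best_idtp) best_idtp <- tot
  }
  idf1 <- if (GT > 0) 2 * best_idtp / (2 * best_idtp + (total_hyp - best_idtp) +
                                         (GT - best_idtp)) else NA
  list(MOTA = as.numeric(1 - (FN + FP + IDS) / GT),
       MOTP = if (nmatch > 0) as.numeric(iou_sum / nmatch) else NA,
       IDF1 = as.numeric(idf1), IDS = as.integer(IDS),
       FN = FN, FP = FP, GT = GT)
}

# Random tiny tracking instance for oracle comparisons.
random_instance <- function(n_obj = 3, n_frames = 4) {
  gt <- NULL; hyp <- NULL
  next_hyp_id <- 100
  for (f in seq_len(n_frames)) {
    for (i in seq_len(n_obj)) {
      if (stats::runif(1) < 0.8) {
        b <- c(stats::runif(1, 0, 60), stats::runif(1, 0, 60),
               stats::runif(1, 8, 20), stats::runif(1, 8, 20))
        gt <- rbind(gt, data.frame(frame = f, id = i, l = b[1], t = b[2],
                                   w = b[3], h = b[4]))
        if (stats::runif(1) < 0.8) {
          # hypothesis near the gt box, sometimes with a switched id
          hid <- if (stats::runif(1) < 0.75) i + 100 else
            sample(c(seq_len(n_obj) + 100, next_hyp_id), 1)
          hyp <- rbind(hyp, data.frame(frame = f, id = hid,
                                       l = b[1] + stats::rnorm(1, 0, 1),
                                       t = b[2] + stats::rnorm(1, 0, 1),
                                       w = b[3], h = b[4]))
        }
      }
    }
    if (stats::runif(1) < 0.3) {
      hyp <- rbind(hyp, data.frame(frame = f, id = next_hyp_id,
                                   l = stats::runif(1, 0, 60),
                                   t = stats::runif(1, 0, 60),
                                   w = stats::runif(1, 8, 20),
                                   h = stats::runif(1, 8, 20)))
      next_hyp_id <- next_hyp_id + 1
    }
  }
  # de-duplicate hyp ids within a frame (oracle precondition)
  if (!is.null(hyp)) {
    keep <- !duplicated(hyp[, c("frame", "id")])
    hyp <- hyp[keep, , drop = FALSE]
  }
  list(gt = gt, hyp = hyp)
}

random_box <- function() {
  c(stats::runif(1, -50, 50), stats::runif(1, -50, 50),
    stats::runif(1, 0.5, 40), stats::runif(1, 0.5, 40))
}
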