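#' Minimum-cost linear assignment with an admissibility gate
#'
#' Solves the rectangular linear assignment problem (Hungarian method,
#' shortest augmenting path) and then demotes any matched pair whose
#' cost exceeds `gate` back to the unmatched pools.  Non-finite costs
#' act as infeasible sentinels.  Used by every association stage:
#' appearance cascade, primary and secondary IOU matching, and the
#' CLEAR-MOT evaluator.
#'
#' @param cost numeric cost matrix (rows = tracks, cols = detections);
#'   may be empty.
#' @param gate maximum admissible cost for a match (default `Inf`).
#' @return A list with `matches` (two-column integer matrix of row/col
#'   indices, ordered by row), `unmatched_rows`, `unmatched_cols`.
#' @examples
#' solve_assignment(rbind(c(1, 2), c(2, 4)))  # picks (1,2) and (2,1)
#' @export
solve_assignment <- function(cost, gate = Inf) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("row", "col")))
  if (n == 0L || m == 0L) {
    return(list(matches = empty,
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m)))
  }
  BIG <- 1e12
  work <- cost
  work[!is.finite(work)] <- BIG
  # offset so costs are bounded; scale-invariant for the argmin
  assign_rc <- hungarian_solve(work)   # length-n vector: col for each row, NA if none
  keep <- which(!is.na(assign_rc))
  if (length(keep)) {
    ok <- cost[cbind(keep, assign_rc[keep])] <= gate &
      work[cbind(keep, assign_rc[keep])] < BIG / 2
    keep <- keep[ok]
  }
  matches <- cbind(row = keep, col = assign_rc[keep])
  matches <- matches[order(matches[, 1L]), , drop = FALSE]
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(n), matches[, 1L]),
       unmatched_cols = setdiff(seq_len(m), matches[, 2L]))
}

# Shortest-augmenting-path Hungarian algorithm for an n x m matrix with
# finite costs.  Assigns min(n, m) pairs minimising total cost; returns
# the assigned column for each row (NA where a row is left out, only
# possible when n > m).
hungarian_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) {
    byrow <- hungarian_solve(t(cost))   # col index -> row
    out <- rep(NA_integer_, n)
    for (j in seq_len(m)) if (!is.na(byrow[j])) out[byrow[j]] <- j
    return(out)
  }
  # n <= m; 1-based ports of the classic potentials formulation with a
  # virtual column m + 1 used as the start of each augmenting search.
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)        # p[j] = row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  out <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] != 0L) out[p[j]] <- j
  out
}
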