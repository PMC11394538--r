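#' MOT-16 and companion file formats
#'
#' MOT-16 detection/ground-truth/result files are 10-field CSV lines
#' `frame, id, bb_left, bb_top, bb_width, bb_height, conf, x, y, z`
#' with 1-based frame indices; detections carry `id = -1`.  Ground
#' truth files with the 9-column MOTChallenge layout (consider-flag,
#' class, visibility) are tolerated and filtered to considered entries.
#' Appearance features travel in a sidecar: a delimiter-separated
#' numeric matrix, one row per detection line of the companion
#' detection file.  Lines starting with `#` are comments.
#'
#' @name io_formats
NULL

#' Read a MOT-16 file
#'
#' @param path file path.
#' @param kind one of `"det"`, `"gt"`, `"result"`.
#' @return A data.frame sorted by `(frame, id)` with columns
#'   `frame, id, l, t, w, h, conf, x, y, z`.
#' @export
read_mot <- function(path, kind = c("det", "gt", "result")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(frame = integer(0), id = integer(0), l = numeric(0),
                      t = numeric(0), w = numeric(0), h = numeric(0),
                      conf = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0))
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L | nf > 10L)
  if (length(bad))
    stop("malformed MOT line ", lineno[bad[1L]], " in ", path,
         ": expected 6-10 comma-separated fields, got ", nf[bad[1L]])
  vals <- suppressWarnings(lapply(fields, as.numeric))
  nn <- vapply(vals, function(v) any(is.na(v)), TRUE)
  if (any(nn))
    stop("malformed MOT line ", lineno[which(nn)[1L]], " in ", path,
         ": non-numeric field")
  if (any(vapply(vals, function(v) any(!is.finite(v)), TRUE)))
    stop("non-finite coordinates in ", path)
  pad <- function(v) c(v, rep(-1, 10L - length(v)))
  m <- do.call(rbind, lapply(vals, pad))
  df <- data.frame(frame = as.integer(m[, 1L]), id = as.integer(m[, 2L]),
                   l = m[, 3L], t = m[, 4L], w = m[, 5L], h = m[, 6L],
                   conf = m[, 7L], x = m[, 8L], y = m[, 9L], z = m[, 10L])
  if (any(df$frame < 1L)) stop("frame indices must be >= 1 in ", path)
  if (any(df$w <= 0 | df$h <= 0)) stop("non-positive box size in ", path)
  if (kind == "gt") {
    # MOTChallenge gt: column 7 is a consider flag, 0 = ignore
    flagged <- nf >= 7L & m[, 7L] == 0
    df <- df[!flagged, , drop = FALSE]
    df$conf <- 1
  }
  df <- df[order(df$frame, df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a MOT-16 file
#'
#' Lines are ordered by `(frame, id)`; box and confidence fields are
#' written with fixed six-decimal precision, so a write/read round trip
#' is exact to 1e-6.
#'
#' @param df data.frame with columns `frame, id, l, t, w, h, conf`
#'   (missing `id` is written as -1; `x, y, z` default to -1).
#' @param path output path.
#' @param header optional comment line(s) written at the top (each
#'   prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_mot <- function(df, path, header = NULL) {
  id <- if ("id" %in% names(df)) df$id else rep(-1L, nrow(df))
  x <- if ("x" %in% names(df)) df$x else rep(-1, nrow(df))
  y <- if ("y" %in% names(df)) df$y else rep(-1, nrow(df))
  z <- if ("z" %in% names(df)) df$z else rep(-1, nrow(df))
  o <- order(df$frame, id)
  lines <- sprintf("%d,%d,%.6f,%.6f,%.6f,%.6f,%.6f,%g,%g,%g",
                   as.integer(df$frame[o]), as.integer(id[o]),
                   df$l[o], df$t[o], df$w[o], df$h[o], df$conf[o],
                   x[o], y[o], z[o])
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read an appearance-feature sidecar matrix
#'
#' @param path text file holding one whitespace- or comma-delimited
#'   numeric row per detection line of the companion detection file.
#' @param expected_rows line count of the companion detection file.
#' @return A numeric matrix with L2-normalised rows.
#' @export
read_feature_sidecar <- function(path, expected_rows) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(gsub(",", " ", l)), "\\s+")[[1L]]))
  if (length(rows) != expected_rows)
    stop("feature sidecar has ", length(rows), " rows but the detection ",
         "file has ", expected_rows, " lines")
  if (!length(rows)) return(matrix(numeric(0), 0L, 0L))
  width <- lengths(rows)
  if (length(unique(width)) != 1L)
    stop("feature sidecar rows have inconsistent widths")
  m <- do.call(rbind, rows)
  if (any(!is.finite(m))) stop("non-finite values in feature sidecar")
  l2_normalize(m)
}

#' Write an appearance-feature sidecar matrix
#'
#' @param m numeric matrix, one embedding per row.
#' @param path output path.
#' @param header optional comment line(s).
#' @return `path`, invisibly.
#' @export
write_feature_sidecar <- function(m, path, header = NULL) {
  lines <- apply(as.matrix(m), 1L, function(r)
    paste(sprintf("%.8f", r), collapse = " "))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' DarkLabel CSV dialect description
#'
#' DarkLabel exports per-frame box annotations in several CSV layouts;
#' a dialect names the column order and the frame-index base.  The
#' default dialect is `frame, id, x, y, w, h` with 0-based frames.
#'
#' @param columns character vector naming, in file order, the columns;
#'   must contain `frame`, `id`, `x`, `y`, `w`, `h`.
#' @param frame_base 0 or 1: the file's frame-index origin.
#' @return A `darklabel_dialect` list.
#' @export
darklabel_dialect <- function(columns = c("frame", "id", "x", "y", "w", "h"),
                              frame_base = 0L) {
  required <- c("frame", "id", "x", "y", "w", "h")
  if (!all(required %in% columns))
    stop("dialect must declare columns: ",
         paste(setdiff(required, columns), collapse = ", "))
  if (!frame_base %in% c(0L, 1L)) stop("frame_base must be 0 or 1")
  structure(list(columns = columns, frame_base = as.integer(frame_base)),
            class = "darklabel_dialect")
}

#' Convert a DarkLabel annotation CSV to a MOT-16 ground-truth file
#'
#' Ids are preserved; frame indices are normalised to the 1-based
#' MOT-16 convention.
#'
#' @param path DarkLabel CSV path.
#' @param out output MOT-16 gt path.
#' @param dialect a [darklabel_dialect()].
#' @return `out`, invisibly.
#' @export
convert_darklabel <- function(path, out, dialect = darklabel_dialect()) {
  if (!inherits(dialect, "darklabel_dialect")) stop("unknown dialect")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && any(nf != length(dialect$columns)))
    stop("line ", which(nf != length(dialect$columns))[1L],
         ": expected ", length(dialect$columns), " columns, got ",
         nf[nf != length(dialect$columns)][1L])
  col <- function(name) {
    i <- match(name, dialect$columns)
    vapply(fields, function(f) as.numeric(f[i]), 0)
  }
  frame <- as.integer(col("frame")) + (1L - dialect$frame_base)
  df <- data.frame(frame = frame, id = as.integer(col("id")),
                   l = col("x"), t = col("y"), w = col("w"), h = col("h"),
                   conf = rep(1, length(frame)))
  if (nrow(df) && any(!is.finite(as.matrix(df)))) stop("non-finite values in ", path)
  write_mot(df, out)
  invisible(out)
}

#' Export ground truth as a Market-1501-style re-identification dataset
#'
#' One crop file per (frame, id), named
#' `personID_c<camera>s1_frameID_00`, split per identity into `train/`
#' and `val/` directories by the given ratio (earliest frames go to
#' the training split).  When no frame images are available the crops
#' are placeholder text files recording the source box, which is
#' sufficient for pipeline and file-count tests.
#'
#' @param gt MOT-16 gt file path or equivalent data.frame; ids must be
#'   positive.
#' @param out_dir output directory (created).
#' @param train_ratio per-identity fraction of crops sent to the
#'   training split (default 0.5).
#' @param camera_id camera number used in filenames (default 1: one
#'   camera per pen).
#' @param ext crop filename extension (default `".txt"`, placeholder
#'   crops).
#' @return Invisibly, a data.frame manifest of written files.
#' @export
export_market1501 <- function(gt, out_dir, train_ratio = 0.5,
                              camera_id = 1L, ext = ".txt") {
  if (is.character(gt)) gt <- read_mot(gt, kind = "gt")
  if (any(gt$id <= 0)) stop("re-identification export requires positive ids")
  dir.create(file.path(out_dir, "train"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "val"), recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL
  for (pid in sort(unique(gt$id))) {
    rows <- gt[gt$id == pid, , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    n <- nrow(rows)
    n_train <- ceiling(train_ratio * n)
    for (k in seq_len(n)) {
      split <- if (k <= n_train) "train" else "val"
      fn <- sprintf("%04d_c%ds1_%06d_00%s", pid, as.integer(camera_id),
                    rows$frame[k], ext)
      path <- file.path(out_dir, split, fn)
      writeLines(sprintf("frame=%d id=%d box=%.2f,%.2f,%.2f,%.2f",
                         rows$frame[k], pid, rows$l[k], rows$t[k],
                         rows$w[k], rows$h[k]), path)
      manifest <- rbind(manifest,
                        data.frame(id = pid, frame = rows$frame[k],
                                   split = split, path = path))
    }
  }
  invisible(manifest)
}
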