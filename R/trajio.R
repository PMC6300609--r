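#' Column dialects for localization tables
#'
#' A dialect maps the standard internal column names (`frame`, `x_nm`, `y_nm`,
#' `sigma_nm`, `photons`) to the header names found in a particular export
#' format. [thunderstorm_dialect()] matches the ThunderSTORM CSV export.
#'
#' @return Named character vector: names are internal columns, values are the
#'   header names expected in the file.
#' @export
default_dialect <- function() {
  c(frame = "frame", x_nm = "x_nm", y_nm = "y_nm",
    sigma_nm = "sigma_nm", photons = "photons")
}

#' @rdname default_dialect
#' @export
thunderstorm_dialect <- function() {
  c(frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
    sigma_nm = "sigma [nm]", photons = "intensity [photon]")
}

#' Read a localization table
#'
#' Reads one detected emitter per row from a CSV export (one row per emitter
#' per frame). Required columns: frame, x, y; localization precision and
#' photon count are optional. Input row order is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Named character vector mapping internal column names to the
#'   file's header names; see [default_dialect()].
#' @return A `data.frame` with columns `frame` (integer, 0-based allowed),
#'   `x_nm`, `y_nm`, `sigma_nm`, `photons` (the latter two `NA` when absent).
#' @export
read_localizations <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  required <- c("frame", "x_nm", "y_nm")
  for (col in required) {
    if (!(dialect[[col]] %in% names(raw))) {
      stop("missing required column '", dialect[[col]], "' in ", path)
    }
  }
  parse_num <- function(col) {
    src <- dialect[[col]]
    if (!(src %in% names(raw))) return(rep(NA_real_, nrow(raw)))
    v <- suppressWarnings(as.numeric(raw[[src]]))
    bad <- which(is.na(v) & !is.na(raw[[src]]) & nzchar(trimws(raw[[src]])))
    if (length(bad)) {
      stop("non-numeric value '", raw[[src]][bad[1]], "' in column '", src,
           "' at data row ", bad[1])
    }
    v
  }
  locs <- data.frame(
    frame = parse_num("frame"),
    x_nm = parse_num("x_nm"),
    y_nm = parse_num("y_nm"),
    sigma_nm = parse_num("sigma_nm"),
    photons = parse_num("photons")
  )
  if (nrow(locs)) {
    if (any(is.na(locs$frame))) stop("missing frame value in ", path)
    if (any(locs$frame < 0)) stop("negative frame index in ", path)
    if (any(!is.na(locs$sigma_nm) & locs$sigma_nm <= 0)) {
      stop("localization precision must be positive")
    }
    locs$frame <- as.integer(round(locs$frame))
  } else {
    locs$frame <- integer(0)
  }
  locs
}

#' Write a localization table
#'
#' Inverse of [read_localizations()]: writes the standard columns under the
#' header names given by `dialect`, dropping all-`NA` optional columns.
#'
#' @param locs Localization data frame as returned by [read_localizations()].
#' @param path Output CSV path.
#' @inheritParams read_localizations
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, dialect = default_dialect()) {
  out <- data.frame(frame = locs$frame, check.names = FALSE)
  out[[dialect[["x_nm"]]]] <- locs$x_nm
  out[[dialect[["y_nm"]]]] <- locs$y_nm
  names(out)[1] <- dialect[["frame"]]
  if (!all(is.na(locs$sigma_nm))) out[[dialect[["sigma_nm"]]]] <- locs$sigma_nm
  if (!all(is.na(locs$photons))) out[[dialect[["photons"]]]] <- locs$photons
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify the DNA axis on the image
#'
#' @param origin Numeric length-2, axis origin in nm (image frame).
#' @param direction Numeric length-2 direction; normalized internally.
#' @param length DNA contour span on the image, nm (informational).
#' @return An object of class `axis_spec`.
#' @export
axis_spec <- function(origin = c(0, 0), direction = c(1, 0), length = 4100) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm <= 0) stop("invalid axis: zero-length direction")
  if (length <= 0) stop("invalid axis: length must be positive")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm,
                 length = length),
            class = "axis_spec")
}

#' Fit the DNA axis to a localization cloud
#'
#' Total-least-squares line through the (x, y) cloud (first principal
#' component), for data sets where the axis endpoints were not recorded.
#'
#' @param locs Localization data frame.
#' @return An `axis_spec` with origin at the cloud centroid.
#' @export
fit_axis <- function(locs) {
  if (nrow(locs) < 2) stop("need at least 2 localizations to fit an axis")
  xy <- cbind(locs$x_nm, locs$y_nm)
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr))
  dir <- sv$v[, 1]
  if (dir[1] < 0) dir <- -dir
  span <- diff(range(xy %*% dir))
  axis_spec(origin = ctr, direction = dir, length = max(span, 1))
}

#' Rotate localizations onto the DNA axis
#'
#' Applies the rigid transform that maps the axis origin to (0, 0) and the
#' axis direction onto +x, so the on-axis coordinate becomes `x_nm` and the
#' off-axis offset `y_nm`. Pairwise distances are preserved.
#'
#' @param locs Localization data frame.
#' @param axis An [axis_spec()].
#' @return The localizations in the rotated frame.
#' @export
align_to_axis <- function(locs, axis) {
  stopifnot(inherits(axis, "axis_spec"))
  d <- axis$direction
  # rows of the rotation matrix taking d -> (1, 0)
  x <- (locs$x_nm - axis$origin[1]) * d[1] + (locs$y_nm - axis$origin[2]) * d[2]
  y <- -(locs$x_nm - axis$origin[1]) * d[2] + (locs$y_nm - axis$origin[2]) * d[1]
  out <- locs
  out$x_nm <- x
  out$y_nm <- y
  out
}

#' Construct a track table
#'
#' @param df Data frame with columns `track_id`, `frame`, `s_nm`, `y_nm`,
#'   `bridged`.
#' @param frame_interval Frame interval in seconds.
#' @return A `scan_tracks` data frame.
#' @export
scan_tracks <- function(df, frame_interval) {
  stopifnot(all(c("track_id", "frame", "s_nm", "y_nm", "bridged") %in% names(df)),
            frame_interval > 0)
  ord <- order(df$track_id, df$frame)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  for (id in unique(df$track_id)) {
    fr <- df$frame[df$track_id == id]
    gaps <- diff(fr)
    if (any(gaps < 1 | gaps > 2)) {
      stop("track ", id, ": frames must increase by 1 (contiguous) or 2 (bridged blink)")
    }
  }
  structure(df, class = c("scan_tracks", "data.frame"),
            frame_interval = frame_interval)
}

#' @export
print.scan_tracks <- function(x, ...) {
  ids <- unique(x$track_id)
  cat("scan_tracks: ", length(ids), " track(s), ", nrow(x), " localizations, ",
      "frame interval ", attr(x, "frame_interval") * 1e3, " ms\n", sep = "")
  invisible(x)
}

#' Frame interval of a track table
#' @param tracks A `scan_tracks` object.
#' @return Frame interval in seconds.
#' @export
frame_interval <- function(tracks) attr(tracks, "frame_interval")

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking. A localization in frame f
#' extends a track whose last detection was in frame f-1 (within `gate` nm) or
#' in frame f-2 (within `bridge_gate` nm, bridging a single blinked frame).
#' Assignments are made in order of increasing distance; ties break to the
#' lowest track id. Unmatched localizations start new tracks, so linking
#' partitions the input.
#'
#' @param locs Axis-aligned localization data frame (x is the on-axis
#'   coordinate).
#' @param frame_interval Frame interval, seconds.
#' @param gate Maximum displacement between consecutive frames, nm.
#' @param bridge_gate Maximum displacement across a one-frame gap, nm.
#' @return A [scan_tracks()] table; `bridged` flags the frames flanking each
#'   bridged one-frame gap.
#' @export
link_tracks <- function(locs, frame_interval, gate = 600, bridge_gate = 600) {
  stopifnot(gate > 0, bridge_gate > 0)
  n <- nrow(locs)
  empty <- scan_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                  s_nm = numeric(0), y_nm = numeric(0),
                                  bridged = logical(0)), frame_interval)
  if (n == 0) return(empty)
  locs <- locs[order(locs$frame), , drop = FALSE]
  track_id <- integer(n)
  bridged <- logical(n)
  # active track state: id, last frame, last position, row of last point
  act_id <- integer(0); act_fr <- integer(0)
  act_x <- numeric(0); act_y <- numeric(0); act_row <- integer(0)
  next_id <- 1L
  frames <- sort(unique(locs$frame))
  for (f in frames) {
    keep <- act_fr >= f - 2L
    act_id <- act_id[keep]; act_fr <- act_fr[keep]
    act_x <- act_x[keep]; act_y <- act_y[keep]; act_row <- act_row[keep]
    rows <- which(locs$frame == f)
    if (length(act_id)) {
      lag <- f - act_fr
      dx <- outer(act_x, locs$x_nm[rows], "-")
      dy <- outer(act_y, locs$y_nm[rows], "-")
      dist <- sqrt(dx^2 + dy^2)
      lim <- ifelse(lag == 1L, gate, bridge_gate)
      dist[dist > lim] <- Inf
      taken_loc <- logical(length(rows))
      repeat {
        dmin <- suppressWarnings(min(dist))
        if (!is.finite(dmin)) break
        hit <- which(dist == dmin, arr.ind = TRUE)
        # tie-break: smallest distance first, then lowest track id
        hit <- hit[order(act_id[hit[, 1]]), , drop = FALSE]
        i <- hit[1, 1]
        j <- hit[1, 2]
        row <- rows[j]
        track_id[row] <- act_id[i]
        if (lag[i] == 2L) {
          bridged[row] <- TRUE
          bridged[act_row[i]] <- TRUE
        }
        act_fr[i] <- f; act_x[i] <- locs$x_nm[row]
        act_y[i] <- locs$y_nm[row]; act_row[i] <- row
        taken_loc[j] <- TRUE
        dist[i, ] <- Inf
        dist[, j] <- Inf
      }
      new_rows <- rows[!taken_loc]
    } else {
      new_rows <- rows
    }
    for (row in new_rows) {
      track_id[row] <- next_id
      act_id <- c(act_id, next_id); act_fr <- c(act_fr, f)
      act_x <- c(act_x, locs$x_nm[row]); act_y <- c(act_y, locs$y_nm[row])
      act_row <- c(act_row, row)
      next_id <- next_id + 1L
    }
  }
  scan_tracks(data.frame(track_id = track_id, frame = locs$frame,
                         s_nm = locs$x_nm, y_nm = locs$y_nm,
                         bridged = bridged), frame_interval)
}

#' Apply the trajectory quality filters
#'
#' Retains tracks that (i) stay within `band` nm of the DNA axis at every
#' frame, (ii) persist for more than `min_frames` frames (i.e. at least
#' `min_frames + 1` detections), and (iii) span at least `min_range` nm along
#' the axis. Filtering is idempotent.
#'
#' @param tracks A [scan_tracks()] table.
#' @param min_frames Tracks must have strictly more detections than this.
#' @param min_range Minimum positional range `max(s) - min(s)`, nm.
#' @param band Maximum |off-axis offset|, nm.
#' @return List with `tracks` (retained, a `scan_tracks`) and `rejected`, a
#'   named count of tracks removed by the first rule each violated
#'   (`boundary`, `length`, `range`).
#' @export
filter_tracks <- function(tracks, min_frames = 5, min_range = 300, band = 200) {
  ids <- unique(tracks$track_id)
  rej <- c(boundary = 0L, length = 0L, range = 0L)
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], ]
    if (any(abs(tr$y_nm) > band)) {
      rej["boundary"] <- rej["boundary"] + 1L
    } else if (nrow(tr) <= min_frames) {
      rej["length"] <- rej["length"] + 1L
    } else if (diff(range(tr$s_nm)) < min_range) {
      rej["range"] <- rej["range"] + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  out <- tracks[tracks$track_id %in% ids[keep], , drop = FALSE]
  rownames(out) <- NULL
  list(tracks = scan_tracks(out, frame_interval(tracks)), rejected = rej)
}

#' Write / read a track table
#'
#' Tracks serialize to CSV with columns `track_id`, `frame`, `s_nm`, `y_nm`,
#' `bridged`; the frame interval is stored in a `# frame_interval_s=` comment
#' on the first line.
#'
#' @param tracks A [scan_tracks()] table.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the `scan_tracks` (reader).
#' @export
write_tracks <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_s=%.17g", frame_interval(tracks)), con)
  utils::write.csv(as.data.frame(tracks), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  first <- readLines(path, n = 1)
  dt <- as.numeric(sub("^# frame_interval_s=", "", first))
  if (!is.finite(dt)) stop("missing frame_interval header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  df$bridged <- as.logical(df$bridged)
  scan_tracks(df, dt)
}
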