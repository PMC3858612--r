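#' Construct a Trajectory
#'
#' @param id individual identifier.
#' @param t fix times. Either numeric seconds or anything coercible by
#'   [as.POSIXct()]; converted to numeric seconds internally.
#' @param x,y planar coordinates in meters (local study grid).
#' @param sex `"M"`, `"F"` or `NA`.
#' @param night night identifier; `"pooled"` for data merged across nights.
#' @param inSight logical vector; recycled, defaults to all `TRUE`.
#' @return a [Trajectory-class] object.
#' @examples
#' tr <- Trajectory("f1", t = c(0, 300, 600), x = c(0, 3, 3),
#'                  y = c(0, 4, 4), sex = "F")
#' pathLength(tr)
#' @export
Trajectory <- function(id, t, x, y, sex = NA_character_, night = "pooled",
                       inSight = TRUE) {
  if (inherits(t, "POSIXt")) t <- as.numeric(t)
  if (is.character(t)) t <- as.numeric(as.POSIXct(t, tz = "UTC"))
  ord <- order(t)
  n <- length(t)
  new("Trajectory", id = as.character(id), sex = as.character(sex),
      night = as.character(night), t = as.numeric(t)[ord],
      x = as.numeric(x)[ord], y = as.numeric(y)[ord],
      inSight = rep_len(as.logical(inSight), n)[ord])
}

#' Subsample a trajectory to a minimum fix interval
#'
#' Greedy forward scan: the first fix is always kept, and a subsequent fix
#' is kept iff its time is at least `interval` seconds after the last kept
#' fix. This is the subsampling applied before home-range estimation
#' (default 5-min interval). The operation is idempotent.
#'
#' @param traj a [Trajectory-class].
#' @param interval minimum spacing in seconds (> 0); default 300.
#' @return a [Trajectory-class] with the retained fixes.
#' @export
subsampleFixes <- function(traj, interval = 300) {
  stopifnot(is(traj, "Trajectory"), interval > 0)
  n <- length(traj@t)
  if (n == 0) return(traj)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- traj@t[1]
  for (i in seq_len(n)[-1]) {
    if (traj@t[i] - last >= interval) {
      keep[i] <- TRUE
      last <- traj@t[i]
    }
  }
  new("Trajectory", id = traj@id, sex = traj@sex, night = traj@night,
      t = traj@t[keep], x = traj@x[keep], y = traj@y[keep],
      inSight = traj@inSight[keep])
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean step lengths between consecutive fixes, in meters.
#' A single-fix trajectory has length 0. Used as the velocity input of the
#' random gas encounter model (distance covered per observation period).
#'
#' @param traj a [Trajectory-class] with at least one fix.
#' @return numeric(1), meters.
#' @export
pathLength <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  if (length(traj@t) == 0) stop("pathLength: trajectory has no fixes")
  if (length(traj@t) == 1) return(0)
  sum(sqrt(diff(traj@x)^2 + diff(traj@y)^2))
}

#' Align two simultaneously followed trajectories into a DyadSeries
#'
#' For every fix of `a`, the nearest-in-time unused fix of `b` within
#' `tol` seconds is paired with it (ties broken toward the earlier `b`
#' fix); each `b` fix is used at most once. Fixes of `a` with no match are
#' dropped. The result carries `a`'s times.
#'
#' The default tolerance of 150 s is half the 5-min subsampling grid, so
#' two observers' staggered clocks still pair once per grid step.
#'
#' @param a,b [Trajectory-class] objects; if `sex` slots identify a male
#'   and a female the `DyadSeries` roles follow them, otherwise `a` is
#'   taken as the male.
#' @param tol alignment tolerance in seconds (>= 0).
#' @return a [DyadSeries-class].
#' @export
alignDyad <- function(a, b, tol = 150) {
  stopifnot(is(a, "Trajectory"), is(b, "Trajectory"), tol >= 0)
  na <- length(a@t); nb <- length(b@t)
  ia <- integer(0); ib <- integer(0)
  used <- logical(nb)
  for (i in seq_len(na)) {
    dt <- abs(b@t - a@t[i])
    dt[used] <- Inf
    j <- which.min(dt)           # earliest index on ties
    if (nb > 0 && dt[j] <= tol) {
      ia <- c(ia, i); ib <- c(ib, j)
      used[j] <- TRUE
    }
  }
  swap <- identical(a@sex, "F") && identical(b@sex, "M")
  m <- if (swap) list(id = b@id, x = b@x[ib], y = b@y[ib]) else
    list(id = a@id, x = a@x[ia], y = a@y[ia])
  f <- if (swap) list(id = a@id, x = a@x[ia], y = a@y[ia]) else
    list(id = b@id, x = b@x[ib], y = b@y[ib])
  new("DyadSeries", maleId = m$id, femaleId = f$id, t = a@t[ia],
      mx = m$x, my = m$y, fx = f$x, fy = f$y)
}

#' Inter-partner distances of a DyadSeries
#'
#' @param dy a [DyadSeries-class].
#' @return numeric vector of Euclidean distances (m), one per aligned time.
#' @export
dyadDistances <- function(dy) {
  stopifnot(is(dy, "DyadSeries"))
  sqrt((dy@mx - dy@fx)^2 + (dy@my - dy@fy)^2)
}

#' Read trajectories from CSV
#'
#' Expected columns: `individual_id, sex, night_id, timestamp, x, y` and
#' optionally `in_sight`. Timestamps are ISO-8601 strings or numeric
#' seconds; coordinates decimal meters. Malformed rows (unparseable
#' timestamp or non-finite coordinates) are rejected with their line
#' numbers.
#'
#' @param file path to a CSV file.
#' @param tz time zone for ISO-8601 parsing.
#' @return named list of [Trajectory-class] objects, one per
#'   `individual_id` x `night_id` combination, named `"<id>.<night>"`.
#' @export
readTrajectories <- function(file, tz = "UTC") {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("individual_id", "sex", "night_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$in_sight)) df$in_sight <- TRUE
  tnum <- suppressWarnings(as.numeric(df$timestamp))
  if (anyNA(tnum))
    tnum <- as.numeric(as.POSIXct(df$timestamp, tz = tz,
                                  tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                 "%Y-%m-%d %H:%M:%OS")))
  bad <- which(!is.finite(tnum) | !is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  key <- paste(df$individual_id, df$night_id, sep = ".")
  out <- lapply(split(seq_len(nrow(df)), key), function(i) {
    Trajectory(df$individual_id[i[1]], tnum[i], df$x[i], df$y[i],
               sex = df$sex[i[1]], night = df$night_id[i[1]],
               inSight = as.logical(df$in_sight[i]))
  })
  out
}

#' Write trajectories to CSV
#'
#' Inverse of [readTrajectories()]; timestamps are written as numeric
#' seconds for exact round-tripping.
#'
#' @param trajs list of [Trajectory-class] objects.
#' @param file output path.
#' @export
writeTrajectories <- function(trajs, file) {
  rows <- lapply(trajs, function(tr) {
    data.frame(individual_id = tr@id, sex = tr@sex, night_id = tr@night,
               timestamp = tr@t, x = tr@x, y = tr@y,
               in_sight = tr@inSight)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
}

#' Pool per-night trajectories of one individual
#'
#' @param trajs list of [Trajectory-class] objects sharing an id.
#' @return a single pooled [Trajectory-class] (`night = "pooled"`).
#' @export
poolTrajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  ids <- unique(vapply(trajs, function(x) x@id, ""))
  if (length(ids) != 1) stop("trajectories belong to different individuals")
  Trajectory(ids, t = unlist(lapply(trajs, function(x) x@t)),
             x = unlist(lapply(trajs, function(x) x@x)),
             y = unlist(lapply(trajs, function(x) x@y)),
             sex = trajs[[1]]@sex, night = "pooled",
             inSight = unlist(lapply(trajs, function(x) x@inSight)))
}
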