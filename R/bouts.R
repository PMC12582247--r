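#' Construct a trajectory bout
#'
#' A bout is one continuous locomotion recording: a strictly increasing
#' time vector and, for each marker, a two-column (x = fore-aft,
#' y = lateral) position matrix of the same length. Coordinates are in the
#' species-native length unit; positive x is the travel direction after
#' heading alignment, positive y is left of travel.
#'
#' @param bout_id Bout label.
#' @param species A `species_profile`.
#' @param t Time vector in seconds, strictly increasing.
#' @param positions Named list of n-by-2 matrices (columns x, y), one per
#'   marker; names must cover the profile's legs and body markers.
#' @param provided_contacts Optional data frame of externally supplied
#'   contact events (columns `leg`, `onset_index`, `offset_index`).
#' @param validate Run [validate_bout()] (default `TRUE`).
#' @return An object of class `trajectory_bout`.
#' @export
trajectory_bout <- function(bout_id, species, t, positions,
                            provided_contacts = NULL, validate = TRUE) {
  b <- structure(list(
    bout_id = bout_id, species = species, t = as.numeric(t),
    positions = lapply(positions, function(p) {
      p <- as.matrix(p)
      colnames(p) <- c("x", "y")
      p
    }),
    provided_contacts = provided_contacts
  ), class = "trajectory_bout")
  if (validate) validate_bout(b) else b
}

#' Validate a trajectory bout
#'
#' Checks monotone time, marker coverage and lengths, and finiteness.
#' Markers with a small fraction (at most `max_gap_frac`) of non-finite
#' samples are repaired by linear interpolation; a larger fraction is a
#' validation error. Validation is idempotent: a bout that has passed
#' validation passes again unchanged.
#'
#' @param bout A `trajectory_bout`.
#' @param max_gap_frac Maximum tolerated fraction of non-finite samples per
#'   marker coordinate (default 0.05).
#' @param log Optional drop log environment.
#' @return The validated (possibly gap-filled) bout.
#' @export
validate_bout <- function(bout, max_gap_frac = 0.05, log = NULL) {
  t <- bout$t
  if (any(diff(t) <= 0)) stop("bout ", bout$bout_id, ": time vector not strictly increasing")
  needed <- c(bout$species$leg_labels, bout$species$body_markers)
  missing <- setdiff(needed, names(bout$positions))
  if (length(missing))
    stop("bout ", bout$bout_id, ": missing required marker(s): ",
         paste(missing, collapse = ", "))
  for (m in needed) {
    p <- bout$positions[[m]]
    if (nrow(p) != length(t))
      stop("bout ", bout$bout_id, ": marker ", m, " length differs from t")
    for (j in 1:2) {
      bad <- !is.finite(p[, j])
      if (any(bad)) {
        if (mean(bad) > max_gap_frac)
          stop("bout ", bout$bout_id, ": marker ", m, " has ",
               round(100 * mean(bad), 1), "% non-finite samples (limit ",
               100 * max_gap_frac, "%)")
        p[, j] <- stats::approx(t[!bad], p[!bad, j], xout = t, rule = 2)$y
        log_drop(log, "gap_interpolated",
                 sprintf("bout %s marker %s: %d samples interpolated",
                         bout$bout_id, m, sum(bad)))
      }
    }
    bout$positions[[m]] <- p
  }
  bout$positions <- bout$positions[needed]
  bout
}

#' @export
print.trajectory_bout <- function(x, ...) {
  cat("<trajectory_bout>", x$bout_id, "(", x$species$name, ")\n")
  cat("  ", length(x$t), "frames,", round(diff(range(x$t)), 2), "s,",
      length(x$positions), "markers\n")
  invisible(x)
}

#' Read trajectory bouts from a canonical long-format CSV
#'
#' The canonical bout file is a long CSV with columns `bout_id`, `t`,
#' `marker`, `x`, `y`; one row per marker per frame. Markers are restricted
#' to those named in the profile. For human-style recordings without a
#' pelvis column, a `pelvis` marker is synthesized at load time as the mean
#' of the four hip markers (`hip_*` columns) when present.
#'
#' @param path CSV file path.
#' @param profile A `species_profile`.
#' @param log Optional drop log environment.
#' @return A list of validated `trajectory_bout`s.
#' @export
load_bouts <- function(path, profile, log = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bout_id", "t", "marker", "x", "y")
  if (!all(req %in% names(df)))
    stop("file does not conform to the canonical bout schema; need columns ",
         paste(req, collapse = ", "))
  needed <- c(profile$leg_labels, profile$body_markers)
  out <- list()
  for (id in unique(df$bout_id)) {
    sub <- df[df$bout_id == id, , drop = FALSE]
    markers <- split(sub, sub$marker)
    if (!("pelvis" %in% names(markers)) && "pelvis" %in% needed) {
      hips <- grep("^hip_", names(markers), value = TRUE)
      if (length(hips) == 4L) {
        hp <- markers[[hips[1]]]
        hp$x <- rowMeans(sapply(hips, function(h) markers[[h]]$x))
        hp$y <- rowMeans(sapply(hips, function(h) markers[[h]]$y))
        hp$marker <- "pelvis"
        markers$pelvis <- hp
      }
    }
    missing <- setdiff(needed, names(markers))
    if (length(missing))
      stop("bout ", id, ": file is missing required marker column(s): ",
           paste(missing, collapse = ", "))
    t <- markers[[needed[1]]]$t
    positions <- lapply(markers[needed], function(mk) {
      mk <- mk[order(mk$t), , drop = FALSE]
      cbind(x = mk$x, y = mk$y)
    })
    out[[length(out) + 1L]] <- validate_bout(
      trajectory_bout(id, profile, sort(t), positions, validate = FALSE),
      log = log)
  }
  out
}

#' Write trajectory bouts to the canonical long-format CSV
#'
#' `load_bouts(write_bouts(b, path), profile)` reproduces `b`'s time and
#' position arrays at double precision (values are serialized with 17
#' significant digits).
#'
#' @param bouts List of `trajectory_bout`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  rows <- lapply(bouts, function(b) {
    do.call(rbind, lapply(names(b$positions), function(m) {
      data.frame(bout_id = b$bout_id, t = b$t, marker = m,
                 x = b$positions[[m]][, "x"], y = b$positions[[m]][, "y"],
                 stringsAsFactors = FALSE)
    }))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bout_id = character(), t = numeric(), marker = character(),
               x = numeric(), y = numeric())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bout_id,t,marker,x,y", con)
  if (nrow(df)) {
    lines <- paste(df$bout_id,
                   formatC(df$t, digits = 17, format = "g"),
                   df$marker,
                   formatC(df$x, digits = 17, format = "g"),
                   formatC(df$y, digits = 17, format = "g"), sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}
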