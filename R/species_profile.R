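#' Describe a legged species for gait analysis
#'
#' A species profile collects the embodiment facts the pipeline needs:
#' which legs exist, how they partition into the two alternating support
#' groups of walking, which markers constitute the body state, the camera
#' frame rate, and the phase grid used for temporal normalization.
#'
#' @param name Species label.
#' @param leg_labels Character vector of leg marker names, ordered anterior
#'   to posterior; within an anterior-posterior level, left before right.
#' @param limb_groups List of two character vectors partitioning
#'   `leg_labels` into the two support groups that alternate in antiphase
#'   during walking (contralateral legs for bipeds, diagonal pairs for a
#'   trot, tripods for hexapods).
#' @param body_markers Character vector of marker names whose positions and
#'   velocities form the body state (e.g. `"pelvis"`, or `c("nose",
#'   "tail_base")`).
#' @param frame_rate Sampling rate in Hz.
#' @param phase_grid_size Integer M, number of samples per normalized gait
#'   cycle. Conventionally set near the average number of frames per cycle.
#' @param straightness_threshold Maximum heading range, in degrees, for a
#'   locomotion segment to count as straight (default 30).
#' @param units Length unit label, informational only (analyses are
#'   unit-covariant or unit-free).
#'
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name, leg_labels, limb_groups, body_markers,
                            frame_rate, phase_grid_size = 50L,
                            straightness_threshold = 30,
                            units = "au") {
  stopifnot(is.character(leg_labels), length(leg_labels) >= 2)
  if (!is.list(limb_groups) || length(limb_groups) != 2L)
    stop("limb_groups must be a list of exactly two leg sets")
  if (!setequal(unlist(limb_groups), leg_labels) ||
      length(intersect(limb_groups[[1]], limb_groups[[2]])) > 0)
    stop("limb_groups must be a 2-set partition covering all legs")
  if (phase_grid_size < 4) stop("phase_grid_size must be >= 4")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  structure(list(
    name = name,
    n_legs = length(leg_labels),
    leg_labels = leg_labels,
    limb_groups = lapply(limb_groups, as.character),
    body_markers = as.character(body_markers),
    frame_rate = frame_rate,
    phase_grid_size = as.integer(phase_grid_size),
    straightness_threshold = straightness_threshold,
    units = units
  ), class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile>", x$name, "\n")
  cat("  legs (", x$n_legs, "): ", paste(x$leg_labels, collapse = ", "), "\n", sep = "")
  cat("  groups: {", paste(x$limb_groups[[1]], collapse = ","), "} / {",
      paste(x$limb_groups[[2]], collapse = ","), "}\n", sep = "")
  cat("  body markers:", paste(x$body_markers, collapse = ", "), "\n")
  cat("  frame rate:", x$frame_rate, "Hz;  phase grid:", x$phase_grid_size, "\n")
  invisible(x)
}

#' Built-in species profiles
#'
#' Ready-made profiles for the three embodiments studied throughout the
#' package: a biped (human-like, pelvis body marker, metres), a quadruped
#' walking in trot (mouse-like, nose and tail-base markers, millimetres),
#' and a hexapod walking in tripod gait (fly-like, head marker,
#' millimetres).
#'
#' @return A `species_profile`.
#' @name builtin_profiles
NULL

#' @rdname builtin_profiles
#' @export
profile_biped <- function() {
  species_profile(
    name = "biped",
    leg_labels = c("foot_left", "foot_right"),
    limb_groups = list("foot_left", "foot_right"),
    body_markers = "pelvis",
    frame_rate = 100, phase_grid_size = 50L, units = "m"
  )
}

#' @rdname builtin_profiles
#' @export
profile_quadruped <- function() {
  species_profile(
    name = "quadruped",
    leg_labels = c("front_left", "front_right", "hind_left", "hind_right"),
    limb_groups = list(c("front_left", "hind_right"),
                       c("front_right", "hind_left")),
    body_markers = c("nose", "tail_base"),
    frame_rate = 80, phase_grid_size = 50L, units = "mm"
  )
}

#' @rdname builtin_profiles
#' @export
profile_hexapod <- function() {
  species_profile(
    name = "hexapod",
    leg_labels = c("front_left", "front_right", "mid_left", "mid_right",
                   "hind_left", "hind_right"),
    limb_groups = list(c("front_left", "mid_right", "hind_left"),
                       c("front_right", "mid_left", "hind_right")),
    body_markers = "head",
    frame_rate = 150, phase_grid_size = 40L, units = "mm"
  )
}

#' Group membership helpers
#'
#' `leg_group()` returns which of the two support groups (1 or 2) a leg
#' belongs to. `opposite_front_limb()` returns the front (most anterior)
#' limb of the opposite group, used as the spatial-normalization reference.
#' `leg_side()` returns +1 for left legs, -1 for right legs, based on the
#' `_left`/`_right` suffix convention of the leg label.
#'
#' @param profile A `species_profile`.
#' @param leg Leg label.
#' @return See description.
#' @export
leg_group <- function(profile, leg) {
  if (leg %in% profile$limb_groups[[1]]) return(1L)
  if (leg %in% profile$limb_groups[[2]]) return(2L)
  stop("unknown leg: ", leg)
}

#' @rdname leg_group
#' @export
opposite_front_limb <- function(profile, leg) {
  other <- profile$limb_groups[[3L - leg_group(profile, leg)]]
  # anterior-most first: leg_labels are ordered anterior -> posterior
  other[order(match(other, profile$leg_labels))][1L]
}

#' @rdname leg_group
#' @export
leg_side <- function(profile, leg) {
  if (grepl("left$", leg)) return(1)
  if (grepl("right$", leg)) return(-1)
  0
}

#' Read or write a species profile as YAML
#'
#' @param path File path.
#' @param profile A `species_profile`.
#' @return `read_species_profile()` returns a `species_profile`;
#'   `write_species_profile()` returns `path` invisibly.
#' @export
read_species_profile <- function(path) {
  y <- yaml::read_yaml(path)
  species_profile(
    name = y$name, leg_labels = y$leg_labels,
    limb_groups = y$limb_groups, body_markers = y$body_markers,
    frame_rate = y$frame_rate,
    phase_grid_size = y$phase_grid_size %||% 50L,
    straightness_threshold = y$straightness_threshold %||% 30,
    units = y$units %||% "au"
  )
}

#' @rdname read_species_profile
#' @export
write_species_profile <- function(profile, path) {
  yaml::write_yaml(unclass(profile)[c("name", "leg_labels", "limb_groups",
                                      "body_markers", "frame_rate",
                                      "phase_grid_size",
                                      "straightness_threshold", "units")],
                   path)
  invisible(path)
}
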