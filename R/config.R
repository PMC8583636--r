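#' Device detector configuration
#'
#' Builds the set of tunable device-side thresholds used by the impact
#' detector, the fall classifier, the sawtooth activity parameterization and
#' the respiratory artifact gate. The defaults are the platform's published
#' personalization values; every deployment may override them per subject.
#'
#' The thresholds, with units:
#' \describe{
#'   \item{vertical_posture_threshold}{m/s^2. Mean gravity projection on the
#'     trunk-longitudinal axis at or above which a segment is classified as
#'     an upright (vertical) posture. Default 6.5.}
#'   \item{fall_energy_threshold}{m^2/s^4. Windowed variance of the
#'     acceleration magnitude that an impact transient must exceed, both for
#'     stage-1 triggering and stage-2 confirmation. Default 0.079.}
#'   \item{horizontal_posture_threshold}{m/s^2. Trunk-axis gravity projection
#'     at or below which a segment is classified as lying (horizontal).
#'     Default 2.5.}
#'   \item{movement_activity_energy_threshold}{m^2/s^4. Energy level above
#'     which the subject is considered to be exercising; also fixes the
#'     hysteresis amplitude floor for sawtooth cycle acceptance.
#'     Default 0.1490.}
#'   \item{resting_energy_threshold}{m^2/s^4. Energy level below which an
#'     epoch is treated as rest (excluded from repetition counting, floored
#'     at 1 MET). Default 0.0306.}
#'   \item{ascending_displacement_threshold}{m. Net upward vertical
#'     displacement beyond which an activity epoch is tagged as ascending
#'     (stair/climb intensity). Default 0.1.}
#'   \item{descending_displacement_threshold}{m (negative). Net downward
#'     vertical displacement at or below which an impact is compatible with
#'     a fall. Default -0.12.}
#'   \item{intense_motion_artifact_threshold}{m/s^2. Deviation of the
#'     acceleration magnitude from static gravity above which concurrent
#'     respiratory cycles are gated as motion artifacts. Default 3.7.}
#'   \item{fs}{Hz. Sampling rate of the acceleration stream. Default 40.}
#' }
#'
#' @param vertical_posture_threshold m/s^2, must exceed the horizontal one.
#' @param fall_energy_threshold m^2/s^4, positive.
#' @param horizontal_posture_threshold m/s^2, positive.
#' @param movement_activity_energy_threshold m^2/s^4, positive, must exceed
#'   the resting threshold.
#' @param resting_energy_threshold m^2/s^4, positive.
#' @param ascending_displacement_threshold m, positive.
#' @param descending_displacement_threshold m, negative.
#' @param intense_motion_artifact_threshold m/s^2, positive.
#' @param fs sampling rate in Hz.
#' @return A `detector_config` object (named list).
#' @examples
#' cfg <- detector_config()
#' cfg$fall_energy_threshold
#' @export
detector_config <- function(vertical_posture_threshold = 6.5,
                            fall_energy_threshold = 0.079,
                            horizontal_posture_threshold = 2.5,
                            movement_activity_energy_threshold = 0.1490,
                            resting_energy_threshold = 0.0306,
                            ascending_displacement_threshold = 0.1,
                            descending_displacement_threshold = -0.12,
                            intense_motion_artifact_threshold = 3.7,
                            fs = 40) {
  cfg <- structure(
    list(
      vertical_posture_threshold = as.numeric(vertical_posture_threshold),
      fall_energy_threshold = as.numeric(fall_energy_threshold),
      horizontal_posture_threshold = as.numeric(horizontal_posture_threshold),
      movement_activity_energy_threshold = as.numeric(movement_activity_energy_threshold),
      resting_energy_threshold = as.numeric(resting_energy_threshold),
      ascending_displacement_threshold = as.numeric(ascending_displacement_threshold),
      descending_displacement_threshold = as.numeric(descending_displacement_threshold),
      intense_motion_artifact_threshold = as.numeric(intense_motion_artifact_threshold),
      fs = as.numeric(fs)
    ),
    class = "detector_config"
  )
  validate_detector_config(cfg)
  cfg
}

validate_detector_config <- function(cfg) {
  pos <- c("vertical_posture_threshold", "fall_energy_threshold",
           "horizontal_posture_threshold", "movement_activity_energy_threshold",
           "resting_energy_threshold", "ascending_displacement_threshold",
           "intense_motion_artifact_threshold", "fs")
  for (nm in pos) {
    v <- cfg[[nm]]
    if (!is.finite(v) || v <= 0) {
      stop("detector_config: `", nm, "` must be > 0 (got ", v, ")",
           call. = FALSE)
    }
  }
  if (!is.finite(cfg$descending_displacement_threshold) ||
      cfg$descending_displacement_threshold >= 0) {
    stop("detector_config: `descending_displacement_threshold` must be < 0 ",
         "(downward displacement is negative; got ",
         cfg$descending_displacement_threshold, ")", call. = FALSE)
  }
  if (cfg$horizontal_posture_threshold >= cfg$vertical_posture_threshold) {
    stop("detector_config: `horizontal_posture_threshold` must be below ",
         "`vertical_posture_threshold`", call. = FALSE)
  }
  if (cfg$resting_energy_threshold >= cfg$movement_activity_energy_threshold) {
    stop("detector_config: `resting_energy_threshold` must be below ",
         "`movement_activity_energy_threshold`", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config>\n")
  for (nm in setdiff(names(x), "fs")) {
    cat(sprintf("  %-36s %g\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-36s %g Hz\n", "fs", x$fs))
  invisible(x)
}

#' Anthropometric subject profile
#'
#' Anthropometric parameters have no defaults: the activity and
#' metabolic-expenditure algorithms refuse to run until the relevant fields
#' are configured for the monitored subject.
#'
#' @param weight body weight in kg.
#' @param birth_date `Date` or "YYYY-MM-DD" string.
#' @param gender free-form string (e.g. "female").
#' @param height standing height in cm.
#' @param thorax_perimeter thorax perimeter in cm (vest sizing).
#' @return A `person_profile` object; unset fields are `NA`.
#' @examples
#' person_profile(weight = 75.7, height = 175)
#' @export
person_profile <- function(weight = NA_real_, birth_date = NA,
                           gender = NA_character_, height = NA_real_,
                           thorax_perimeter = NA_real_) {
  if (!is.na(weight) && weight <= 0) {
    stop("person_profile: `weight` must be positive", call. = FALSE)
  }
  if (!is.na(height) && height <= 0) {
    stop("person_profile: `height` must be positive", call. = FALSE)
  }
  bd <- if (length(birth_date) == 1 && is.na(birth_date)) as.Date(NA) else as.Date(birth_date)
  structure(
    list(weight = as.numeric(weight), birth_date = bd,
         gender = as.character(gender), height = as.numeric(height),
         thorax_perimeter = as.numeric(thorax_perimeter)),
    class = "person_profile"
  )
}

#' @export
print.person_profile <- function(x, ...) {
  cat("<person_profile>\n")
  cat(sprintf("  weight:           %s kg\n", x$weight))
  cat(sprintf("  birth_date:       %s\n", as.character(x$birth_date)))
  cat(sprintf("  gender:           %s\n", x$gender))
  cat(sprintf("  height:           %s cm\n", x$height))
  cat(sprintf("  thorax_perimeter: %s cm\n", x$thorax_perimeter))
  invisible(x)
}

#' Is the profile complete?
#'
#' @param profile a [person_profile()].
#' @return `TRUE` when every anthropometric field is set.
#' @export
profile_complete <- function(profile) {
  stopifnot(inherits(profile, "person_profile"))
  !anyNA(profile$weight) && !anyNA(profile$birth_date) &&
    !is.na(profile$gender) && !anyNA(profile$height) &&
    !anyNA(profile$thorax_perimeter)
}

#' Load / save a personalization configuration
#'
#' The configuration file is YAML with two sections: `device:` (detector
#' thresholds; unspecified keys take the published defaults) and `profile:`
#' (anthropometrics; unspecified keys load as unset and block dependent
#' operations). `save_config()` followed by `load_config()` is an identity
#' on the stored values.
#'
#' @param path path to a YAML file.
#' @return `load_config()`: a list with elements `device`
#'   ([detector_config()]) and `profile` ([person_profile()]).
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' save_config(detector_config(), person_profile(weight = 80), f)
#' load_config(f)$device$fall_energy_threshold
#' @export
load_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("load_config: cannot parse `", path, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(raw)) raw <- list()
  dev <- raw$device %||% list()
  known <- names(formals(detector_config))
  bad <- setdiff(names(dev), known)
  if (length(bad) > 0) {
    stop("load_config: unknown device parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  device <- do.call(detector_config, dev)
  prof <- raw$profile %||% list()
  badp <- setdiff(names(prof), names(formals(person_profile)))
  if (length(badp) > 0) {
    stop("load_config: unknown profile field(s): ",
         paste(badp, collapse = ", "), call. = FALSE)
  }
  profile <- do.call(person_profile, prof)
  list(device = device, profile = profile)
}

#' @param device a [detector_config()].
#' @param profile a [person_profile()].
#' @rdname load_config
#' @export
save_config <- function(device, profile = person_profile(), path) {
  stopifnot(inherits(device, "detector_config"),
            inherits(profile, "person_profile"))
  prof <- profile[!vapply(profile, function(v) length(v) == 1 && is.na(v), TRUE)]
  if (!is.null(prof$birth_date)) prof$birth_date <- as.character(prof$birth_date)
  yaml::write_yaml(list(device = unclass(device), profile = prof), path)
  invisible(path)
}
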