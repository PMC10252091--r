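#' Default rigid-body segment model for the right fore- and hindlimb
#'
#' Each segment is defined by a proximal and a distal marker; each joint by
#' an adjacent segment pair. Sagittal flexion/extension is the cardan-x
#' rotation between the two segment frames, with a per-joint sign chosen so
#' that rotation towards the flexor side is positive: the flexor side is
#' caudal for the shoulder, carpus, stifle, MCPJ and MTPJ, and cranial for
#' the elbow, hip and tarsus.
#'
#' @param fore_digit_dist,hind_digit_dist Marker names for the distal end of
#'   the digit segment (defaults match the synthetic generator; map these to
#'   the lateral hoof wall markers for real recordings).
#' @return List with elements `segments` and `joints` (data frames).
#' @export
horse_limb_model <- function(fore_digit_dist = "fore_toe",
                             hind_digit_dist = "hind_toe") {
  segments <- data.frame(
    segment = c("scapula", "humerus", "radius", "metacarpus", "fore_digit",
                "pelvis", "femur", "tibia", "metatarsus", "hind_digit"),
    prox = c("scapula_prox", "shoulder", "elbow", "carpus", "fore_fetlock",
             "tuber_coxae", "hip", "stifle", "tarsus", "hind_fetlock"),
    dist = c("shoulder", "elbow", "carpus", "fore_fetlock", fore_digit_dist,
             "hip", "stifle", "tarsus", "hind_fetlock", hind_digit_dist),
    stringsAsFactors = FALSE)
  joints <- data.frame(
    joint = c("shoulder", "elbow", "carpus", "MCPJ",
              "hip", "stifle", "tarsus", "MTPJ"),
    prox_segment = c("scapula", "humerus", "radius", "metacarpus",
                     "pelvis", "femur", "tibia", "metatarsus"),
    dist_segment = c("humerus", "radius", "metacarpus", "fore_digit",
                     "femur", "tibia", "metatarsus", "hind_digit"),
    sign = c(+1, -1, +1, +1, -1, +1, -1, +1),
    stringsAsFactors = FALSE)
  list(segments = segments, joints = joints)
}

# Segment coordinate frames for every frame of a trial.
# y = longitudinal axis (proximal -> distal marker), x = laboratory lateral
# axis made orthogonal to y, z = x cross y. Returns a list of 3x3 rotation
# matrices stacked in an n x 9 matrix (columns of R in column-major order).
segment_frames <- function(prox, dist, segment = "segment") {
  d <- dist - prox
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-6))
    stop("degenerate segment '", segment, "': coincident markers")
  ey <- d / len
  ex0 <- c(1, 0, 0)
  # remove the component of lab-x along the long axis
  proj <- ey[, 1]                      # ex0 . ey
  ex <- -ey * proj
  ex[, 1] <- ex[, 1] + 1
  exn <- sqrt(rowSums(ex^2))
  if (any(exn < 1e-6))
    stop("degenerate segment '", segment,
         "': longitudinal axis parallel to the lateral axis")
  ex <- ex / exn
  ez <- cbind(ex[, 2] * ey[, 3] - ex[, 3] * ey[, 2],
              ex[, 3] * ey[, 1] - ex[, 1] * ey[, 3],
              ex[, 1] * ey[, 2] - ex[, 2] * ey[, 1])
  cbind(ex, ey, ez)                    # n x 9, columns = (ex, ey, ez)
}

# Cardan x,y,z decomposition of R_rel = t(R_prox) %*% R_dist, vectorized over
# frames; returns the rotation about x (flexion/extension) in radians.
cardan_x_angle <- function(Fp, Fd) {
  # R_rel[2,3] = y_p . z_d ; R_rel[3,3] = z_p . z_d
  r23 <- rowSums(Fp[, 4:6, drop = FALSE] * Fd[, 7:9, drop = FALSE])
  r33 <- rowSums(Fp[, 7:9, drop = FALSE] * Fd[, 7:9, drop = FALSE])
  atan2(-r23, r33)
}

#' Sagittal joint angles from marker trajectories
#'
#' Builds a coordinate frame per segment (longitudinal axis from the marker
#' pair, lateral axis from the laboratory x-axis) and decomposes the
#' relative rotation of each joint's segment pair with the cardan sequence
#' x, y, z; flexion/extension is the rotation about the segment x-axis. When
#' a static standing trial is supplied, each angle series is referenced to
#' the horse's static pose (angles become changes from standing).
#'
#' @param markers A filtered [marker_set].
#' @param model Segment model, see [horse_limb_model()].
#' @param static Optional `marker_set` of the static standing trial.
#' @return Named list of [joint_angle_series], one per joint in the model.
#' @export
compute_joint_angles <- function(markers, model = horse_limb_model(),
                                 static = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  angles <- joint_angles_raw(markers, model)
  if (!is.null(static)) {
    stat <- joint_angles_raw(static, model)
    for (j in names(angles)) {
      angles[[j]] <- normalize_to_static(angles[[j]],
                                         mean(stat[[j]]$values))
    }
  }
  angles
}

joint_angles_raw <- function(markers, model) {
  frames <- list()
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments[i, ]
    for (nm in c(s$prox, s$dist))
      if (is.null(markers$coords[[nm]]))
        stop("model marker '", nm, "' missing from trial")
    frames[[s$segment]] <- segment_frames(markers$coords[[s$prox]],
                                          markers$coords[[s$dist]],
                                          s$segment)
  }
  out <- list()
  for (i in seq_len(nrow(model$joints))) {
    jn <- model$joints[i, ]
    a <- cardan_x_angle(frames[[jn$prox_segment]], frames[[jn$dist_segment]])
    out[[jn$joint]] <- joint_angle_series(jn$joint,
                                          jn$sign * a * 180 / pi,
                                          markers$rate_hz)
  }
  out
}

#' Reference a joint angle series to the static standing pose
#'
#' @param series A [joint_angle_series].
#' @param static_angle Static-trial angle in degrees (same convention).
#' @return The series minus `static_angle`, with `normalized = TRUE`.
#' @export
normalize_to_static <- function(series, static_angle) {
  stopifnot(inherits(series, "joint_angle_series"), is.finite(static_angle))
  series$values <- series$values - static_angle
  series$normalized <- TRUE
  series$static_angle <- static_angle
  series
}

#' Joint angular velocity
#'
#' First derivative of angular displacement: central differences in the
#' interior, one-sided at the ends.
#'
#' @param series A [joint_angle_series] in degrees.
#' @return A [joint_angle_series] in deg/s (`unit = "deg_s"`).
#' @export
angular_velocity <- function(series) {
  stopifnot(inherits(series, "joint_angle_series"))
  joint_angle_series(series$joint, deriv_central(series$values, series$rate_hz),
                     series$rate_hz, normalized = series$normalized,
                     unit = "deg_s")
}

# central-difference derivative with one-sided ends
deriv_central <- function(x, rate_hz) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * rate_hz
  d[n] <- (x[n] - x[n - 1]) * rate_hz
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate_hz / 2
  d
}

#' Limb pro-retraction angle
#'
#' Signed sagittal angle of the limb axis (proximal landmark to lateral hoof
#' wall marker) relative to the downward normal of a body reference axis.
#' The body reference runs from the tubera sacrale marker to a virtual
#' landmark directly above the scapular spine marker (at the tubera sacrale
#' height), so it tracks trunk pitch. Positive = protraction (hoof cranial
#' to the proximal landmark).
#'
#' @param markers A filtered [marker_set].
#' @param limb `"fore"` or `"hind"`.
#' @param proximal,hoof,trunk,withers Marker names; defaults follow the
#'   synthetic generator (scapular spine / tuber coxae proximal landmarks,
#'   lateral hoof wall markers, tubera sacrale and scapular spine trunk
#'   markers).
#' @return A [joint_angle_series] named `fore_proretraction` or
#'   `hind_proretraction`, in degrees.
#' @export
compute_proretraction <- function(markers, limb = c("fore", "hind"),
                                  proximal = NULL, hoof = NULL,
                                  trunk = "tubera_sacrale",
                                  withers = "scapula_prox") {
  limb <- match.arg(limb)
  proximal <- proximal %||% if (limb == "fore") "scapula_prox" else "tuber_coxae"
  hoof <- hoof %||% if (limb == "fore") "fore_hoof" else "hind_hoof"
  for (nm in c(proximal, hoof, trunk, withers))
    if (is.null(markers$coords[[nm]]))
      stop("pro-retraction marker '", nm, "' missing from trial")
  ts <- markers$coords[[trunk]]
  ws <- markers$coords[[withers]]
  # virtual landmark: above the withers marker at tubera sacrale height
  virt <- cbind(ws[, 1], ws[, 2], ts[, 3])
  b <- virt - ts                                 # body reference, cranial
  l <- markers$coords[[hoof]] - markers$coords[[proximal]]
  # sagittal (y, z) components; n = downward normal of the body axis
  by <- b[, 2]; bz <- b[, 3]
  bn <- sqrt(by^2 + bz^2)
  ny <- bz / bn; nz <- -by / bn
  ang <- atan2(ny * l[, 3] - nz * l[, 2], ny * l[, 2] + nz * l[, 3])
  joint_angle_series(paste0(limb, "_proretraction"), ang * 180 / pi,
                     markers$rate_hz)
}
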