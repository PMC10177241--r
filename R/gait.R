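#' Stride event table
#'
#' One row per reference-limb stride: touchdown, liftoff and the next
#' touchdown of the same limb, in seconds. Frame-number inputs should be
#' divided by the recording frame rate first (see
#' [stride_events_from_frames()]).
#'
#' @param reference_limb character label(s) for the reference limb.
#' @param touchdown,liftoff,next_touchdown event times, s; continuous-contact
#'   gait requires `touchdown < liftoff <= next_touchdown`.
#' @return A data.frame of class `stride_events`.
#' @export
stride_events <- function(reference_limb, touchdown, liftoff,
                          next_touchdown) {
  stopifnot(all(is.finite(touchdown)), all(is.finite(liftoff)),
            all(is.finite(next_touchdown)))
  if (any(liftoff <= touchdown)) {
    stop("event ordering violated: liftoff must follow touchdown")
  }
  if (any(next_touchdown < liftoff)) {
    stop("event ordering violated: next touchdown precedes liftoff")
  }
  structure(data.frame(reference_limb = reference_limb,
                       touchdown_s = touchdown, liftoff_s = liftoff,
                       next_touchdown_s = next_touchdown),
            class = c("stride_events", "data.frame"))
}

#' Stride events from video frame numbers
#'
#' Convenience constructor converting frame counts to seconds at the
#' recording frame rate (default 120 Hz lateral video).
#'
#' @param reference_limb limb label(s).
#' @param touchdown_frame,liftoff_frame,next_touchdown_frame frame numbers.
#' @param frame_rate recording frame rate, Hz.
#' @return A [stride_events()] table.
#' @export
stride_events_from_frames <- function(reference_limb, touchdown_frame,
                                      liftoff_frame, next_touchdown_frame,
                                      frame_rate = 120) {
  stopifnot(frame_rate > 0)
  stride_events(reference_limb,
                touchdown_frame / frame_rate,
                liftoff_frame / frame_rate,
                next_touchdown_frame / frame_rate)
}

#' Spatiotemporal stride variables
#'
#' Computes, per stride: contact time (touchdown to liftoff), swing time,
#' stride time (touchdown to next touchdown), duty factor (contact / stride,
#' a fraction), stride frequency (1 / stride time) and stride length
#' (speed x stride time).
#'
#' @param events a [stride_events()] table (one or more strides).
#' @param speed traverse speed, m/s (> 0), recycled across strides.
#' @return A data.frame with columns `contact_time_s`, `swing_time_s`,
#'   `stride_time_s`, `duty_factor`, `stride_frequency_hz`,
#'   `stride_length_m`, `speed_ms`.
#' @export
#' @examples
#' ev <- stride_events("left", 0, 0.75, 1)
#' stride_metrics(ev, speed = 0.6)   # duty factor 0.75, frequency 1 Hz
stride_metrics <- function(events, speed) {
  stopifnot(inherits(events, "stride_events"), all(speed > 0))
  contact <- events$liftoff_s - events$touchdown_s
  stride <- events$next_touchdown_s - events$touchdown_s
  speed <- rep_len(speed, nrow(events))
  data.frame(contact_time_s = contact,
             swing_time_s = stride - contact,
             stride_time_s = stride,
             duty_factor = contact / stride,
             stride_frequency_hz = 1 / stride,
             stride_length_m = speed * stride,
             speed_ms = speed)
}

#' Traverse speed from a head track over a known distance
#'
#' Speed is the marked distance divided by the time taken for the tracked
#' head point to move between the two runway marks, with the crossing
#' instants located by linear interpolation between frames.
#'
#' @param track a [point_track()].
#' @param known_distance marked distance, m (> 0).
#' @param start_mark fore-aft coordinate of the first mark, m; defaults to
#'   the first tracked position.
#' @return Speed, m/s.
#' @export
#' @examples
#' trk <- point_track(seq(0, 2.4, by = 0.005), frame_rate = 120)
#' speed_from_track(trk, 2)  # 0.6 m/s
speed_from_track <- function(track, known_distance, start_mark = NULL) {
  stopifnot(inherits(track, "point_track"), known_distance > 0)
  x <- track$x_m
  t <- track$frame_index / attr(track, "frame_rate")
  if (is.null(start_mark)) start_mark <- x[1]
  end_mark <- start_mark + known_distance
  cross_time <- function(mark) {
    hit <- which(x[-1] >= mark & x[-length(x)] <= mark)
    if (length(hit) == 0) {
      if (abs(x[1] - mark) < 1e-12) return(t[1])
      return(NA_real_)
    }
    i <- hit[1]
    if (x[i + 1] == x[i]) return(t[i])
    t[i] + (mark - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i])
  }
  t1 <- cross_time(start_mark)
  t2 <- cross_time(end_mark)
  if (is.na(t1) || is.na(t2) || t2 <= t1) {
    stop("track never crosses both runway marks")
  }
  known_distance / (t2 - t1)
}
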