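#' Construct an object detection
#'
#' One detected object in one frame. Coordinates are normalised to `[0, 1]`
#' with the origin at the top-left of the image and y increasing downward
#' (image convention).
#'
#' @param label Class label (lowercase snake-case string).
#' @param confidence Detector confidence in `[0, 1]`.
#' @param bbox Numeric vector `(x_min, y_min, width, height)`, normalised.
#' @return An object of class `object_detection`.
#' @export
object_detection <- function(label, confidence, bbox) {
  bbox <- as.numeric(bbox)
  stopifnot(length(bbox) == 4)
  if (confidence < 0 || confidence > 1)
    stop("confidence must be in [0, 1]")
  if (any(bbox[1:2] < 0) || bbox[1] + bbox[3] > 1 + 1e-9 ||
      bbox[2] + bbox[4] > 1 + 1e-9 || any(bbox[3:4] < 0))
    stop("bbox must satisfy 0 <= x_min, y_min and x_min+width <= 1, y_min+height <= 1")
  structure(list(label = as.character(label),
                 confidence = as.numeric(confidence),
                 bbox = bbox),
            class = "object_detection")
}

#' Construct a detection frame
#'
#' @param timestamp_ms Non-negative timestamp in milliseconds.
#' @param detections List of [object_detection()] objects.
#' @param hand_present Logical; whether the hand-tracking module sees a hand.
#' @param hand_centroid Optional normalised `(x, y)` of the hand; only
#'   allowed when `hand_present` is `TRUE`.
#' @return An object of class `frame`.
#' @export
detection_frame <- function(timestamp_ms, detections = list(), hand_present = FALSE,
                  hand_centroid = NULL) {
  if (timestamp_ms < 0) stop("timestamp_ms must be non-negative")
  if (!is.null(hand_centroid) && !hand_present)
    stop("hand_centroid may only be set when hand_present is TRUE")
  structure(list(timestamp_ms = as.numeric(timestamp_ms),
                 detections = detections,
                 hand_present = isTRUE(hand_present),
                 hand_centroid = if (is.null(hand_centroid)) NULL
                                 else as.numeric(hand_centroid)),
            class = "frame")
}

frame_to_json_list <- function(fr) {
  list(
    timestamp_ms = fr$timestamp_ms,
    detections = lapply(fr$detections, function(d)
      list(label = d$label, confidence = d$confidence, bbox = as.list(d$bbox))),
    hand_present = fr$hand_present,
    hand_centroid = if (is.null(fr$hand_centroid)) NULL
                    else as.list(fr$hand_centroid)
  )
}

#' Write a frame stream to a JSON-lines file
#'
#' One frame object per line with keys `timestamp_ms`, `detections`
#' (list of `{label, confidence, bbox:[x, y, w, h]}`), `hand_present` and
#' `hand_centroid` (null when no hand is present). [read_frames()] restores
#' the stream exactly.
#'
#' @param frames List of [detection_frame()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  lines <- vapply(frames, function(fr)
    jsonlite::toJSON(frame_to_json_list(fr), auto_unbox = TRUE,
                     null = "null", digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a frame stream from a JSON-lines file
#'
#' Frames are returned in file order. Timestamps must be strictly
#' increasing; a violation is reported with the offending line number, as is
#' any malformed JSON line. An empty file yields an empty stream.
#'
#' @param path Path to a JSONL frame file.
#' @return List of [detection_frame()] objects.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("frame file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  frames <- vector("list", length(lines))
  last_ts <- -Inf
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop("malformed frame at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    ts <- as.numeric(obj$timestamp_ms)
    if (!is.finite(ts))
      stop("malformed frame at line ", i, ": missing timestamp_ms",
           call. = FALSE)
    if (ts <= last_ts)
      stop("non-monotone timestamp at line ", i, ": ", ts,
           " follows ", last_ts, call. = FALSE)
    last_ts <- ts
    dets <- lapply(obj$detections, function(d)
      object_detection(d$label, d$confidence, unlist(d$bbox)))
    hc <- obj$hand_centroid
    frames[[i]] <- detection_frame(ts, dets, isTRUE(obj$hand_present),
                         if (is.null(hc)) NULL else unlist(hc))
  }
  frames
}

#' Per-frame presence values for a class vocabulary
#'
#' The raw signal the rolling average runs over. In `"confidence"` mode the
#' per-frame presence of a class is the maximum confidence among its
#' detections in that frame (0 if absent); in `"binary"` mode it is 1 if the
#' class is detected at all, else 0.
#'
#' @param frames List of frames.
#' @param class_vocabulary Character vector of class labels (columns).
#' @param mode `"confidence"` (default) or `"binary"`.
#' @return Numeric matrix, frames x classes.
#' @export
presence_matrix <- function(frames, class_vocabulary,
                            mode = c("confidence", "binary")) {
  mode <- match.arg(mode)
  m <- matrix(0, nrow = length(frames), ncol = length(class_vocabulary),
              dimnames = list(NULL, class_vocabulary))
  for (i in seq_along(frames)) {
    for (d in frames[[i]]$detections) {
      j <- match(d$label, class_vocabulary)
      if (is.na(j)) next
      val <- if (mode == "binary") 1 else d$confidence
      if (val > m[i, j]) m[i, j] <- val
    }
  }
  m
}

#' Rolling-average stabilisation of a detection stream
#'
#' Smooths per-frame class presence with a trailing rolling average: for
#' frame k (1-based) the smoothed presence of class c is the mean of the
#' per-frame presence of c over the last `min(window, k)` frames. Warm-up
#' frames therefore average over the frames available so far rather than
#' being dropped — the guidance loop must react from the first frame. One
#' smoothed state is produced per input frame, at the same timestamp. The
#' hand-presence flag is smoothed the same way (as 0/1).
#'
#' @param frames List of frames.
#' @param window Positive integer window size in frames (default 5,
#'   matching the deployed system's 5-frame rolling average).
#' @param class_vocabulary Classes to track; classes absent from the
#'   vocabulary have implicit presence 0.
#' @param mode Per-frame presence definition; see [presence_matrix()].
#' @return An object of class `smoothed_stream`: a list with
#'   `timestamp_ms` (numeric vector), `presence` (frames x classes matrix of
#'   scores in `[0, 1]`), `hand` (numeric vector) and `window`.
#' @export
smooth_frames <- function(frames, window = 5L, class_vocabulary,
                          mode = c("confidence", "binary")) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  raw <- presence_matrix(frames, class_vocabulary, mode)
  hand_raw <- vapply(frames, function(fr) as.numeric(fr$hand_present), 0)
  n <- length(frames)
  sm <- raw
  hand <- hand_raw
  if (n > 0 && window > 1) {
    cs <- apply(raw, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
    ch <- cumsum(hand_raw)
    k <- seq_len(n)
    denom <- pmin(k, window)
    lag <- k - denom                      # index of frame just before window
    num <- cs
    has_lag <- lag > 0
    if (any(has_lag))
      num[has_lag, ] <- cs[has_lag, , drop = FALSE] -
        cs[lag[has_lag], , drop = FALSE]
    sm <- num / denom
    hand <- ch
    if (any(has_lag)) hand[has_lag] <- ch[has_lag] - ch[lag[has_lag]]
    hand <- hand / denom
  }
  colnames(sm) <- class_vocabulary
  structure(list(timestamp_ms = vapply(frames, `[[`, 0, "timestamp_ms"),
                 presence = sm, hand = hand, window = window),
            class = "smoothed_stream")
}

#' @export
print.smoothed_stream <- function(x, ...) {
  cat(sprintf("<smoothed_stream> %d frames, %d classes, window %d\n",
              length(x$timestamp_ms), ncol(x$presence), x$window))
  invisible(x)
}

#' Class presence decision on a smoothed state
#'
#' @param smoothed A `smoothed_stream` from [smooth_frames()].
#' @param i Frame position (1-based).
#' @param class_label Class to test; classes outside the tracked vocabulary
#'   have implicit presence 0.
#' @param threshold Decision threshold in `(0, 1)`; the comparison is
#'   inclusive (presence `>= threshold` counts as present).
#' @return Logical.
#' @export
is_present <- function(smoothed, i, class_label, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  j <- match(class_label, colnames(smoothed$presence))
  if (is.na(j)) return(FALSE)
  smoothed$presence[i, j] >= threshold
}

bbox_center <- function(bbox) c(bbox[1] + bbox[3] / 2, bbox[2] + bbox[4] / 2)

bbox_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

#' Evaluate a spatial relation between two detections
#'
#' Relations (image coordinates, y increasing downward):
#' * `contains` — the subject's bbox centre lies inside the object's bbox;
#' * `overlaps` — the two bboxes have intersection-over-union > 0;
#' * `above` — the subject's bbox centre has smaller y than the object's.
#'
#' @param relation One of `"contains"`, `"overlaps"`, `"above"`.
#' @param subject,object [object_detection()] objects.
#' @return Logical.
#' @export
evaluate_spatial <- function(relation, subject, object) {
  sa <- subject$bbox; ob <- object$bbox
  switch(relation,
    contains = {
      c0 <- bbox_center(sa)
      c0[1] >= ob[1] && c0[1] <= ob[1] + ob[3] &&
        c0[2] >= ob[2] && c0[2] <= ob[2] + ob[4]
    },
    overlaps = bbox_iou(sa, ob) > 0,
    above = bbox_center(sa)[2] < bbox_center(ob)[2],
    stop("unknown spatial relation: ", relation)
  )
}

#' Highest-confidence detection of a class in a frame
#'
#' Duplicate detections of one class are resolved deterministically: highest
#' confidence wins, ties broken by smaller `x_min`, then smaller `y_min`.
#'
#' @param fr A [detection_frame()].
#' @param label Class label.
#' @return An `object_detection`, or `NULL` when the class is not detected.
#' @export
best_detection <- function(fr, label) {
  cand <- Filter(function(d) d$label == label, fr$detections)
  if (!length(cand)) return(NULL)
  ord <- order(-vapply(cand, `[[`, 0, "confidence"),
               vapply(cand, function(d) d$bbox[1], 0),
               vapply(cand, function(d) d$bbox[2], 0))
  cand[[ord[1]]]
}
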