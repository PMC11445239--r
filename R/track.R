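#' Link localizations into tracks by nearest-neighbour assignment
#'
#' Greedy frame-to-frame linking: each localization is connected to the
#' nearest active track end within \code{max_disp_px}; ties are resolved by
#' distance (closest pair first). Tracks survive up to \code{max_gap} missing
#' frames; unmatched localizations start new tracks.
#'
#' @param locs localization data.frame with at least \code{frame},
#'   \code{x_px}, \code{y_px} (only accepted rows should be passed).
#' @param max_disp_px maximum displacement per frame step, pixels.
#' @param max_gap number of missing frames a track may bridge.
#' @return the input rows with a \code{track_id} column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(locs, max_disp_px = 3, max_gap = 1) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(locs)),
            max_disp_px > 0, max_gap >= 0)
  if (nrow(locs) == 0) {
    locs$track_id <- integer(0)
    return(locs)
  }
  if (anyNA(locs$frame)) stop("localizations must carry frame indices")
  locs <- locs[order(locs$frame), , drop = FALSE]
  locs$track_id <- NA_integer_
  next_id <- 1L
  # active track ends: id, x, y, last frame
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    last = integer(0))
  for (f in sort(unique(locs$frame))) {
    act <- act[f - act$last <= max_gap + 1L, , drop = FALSE]
    rows <- which(locs$frame == f)
    if (nrow(act) > 0 && length(rows) > 0) {
      # allowed displacement scales with the bridged gap
      d <- outer(act$x, locs$x_px[rows], `-`)^2 +
           outer(act$y, locs$y_px[rows], `-`)^2
      lim <- (max_disp_px * (f - act$last))^2
      d[d > matrix(lim, nrow(act), length(rows))] <- Inf
      while (any(is.finite(d))) {
        ij <- arrayInd(which.min(d), dim(d))
        a <- ij[1]; r <- rows[ij[2]]
        locs$track_id[r] <- act$id[a]
        act$x[a] <- locs$x_px[r]; act$y[a] <- locs$y_px[r]; act$last[a] <- f
        d[a, ] <- Inf; d[, ij[2]] <- Inf
      }
    }
    new <- rows[is.na(locs$track_id[rows])]
    if (length(new) > 0) {
      ids <- next_id + seq_along(new) - 1L
      locs$track_id[new] <- ids
      next_id <- next_id + length(new)
      act <- rbind(act, data.frame(id = ids, x = locs$x_px[new],
                                   y = locs$y_px[new], last = f))
    }
  }
  locs[order(locs$track_id, locs$frame), , drop = FALSE]
}

#' Classify tracks as immobile or mobile
#'
#' A track is immobile when it spans at least \code{min_immobile_frames}
#' frames and its root-mean-square deviation from its mean position stays
#' within \code{spread_mult} times the localization precision (i.e. the
#' particle exhibits the same localization over time, up to measurement
#' noise). A track is mobile when it contains at least
#' \code{min_mobile_frames} consecutive frame-to-frame displacements, each
#' exceeding \code{step_mult} times the precision. All other tracks are
#' unclassified and excluded from the percentages.
#'
#' @param tracks data.frame from \code{\link{link_tracks}} (columns
#'   \code{track_id}, \code{frame}, \code{x_px}, \code{y_px}).
#' @param precision_px localization precision in pixels (> 0).
#' @param min_immobile_frames minimum duration for the immobile call
#'   (default 10).
#' @param min_mobile_frames minimum persistence of above-noise displacement
#'   for the mobile call (default 5).
#' @param spread_mult positional-spread bound, multiples of the precision.
#' @param step_mult per-step displacement bound, multiples of the precision.
#' @param first_n_frames restrict the analysis to the first N frames of the
#'   movie (e.g. 100), or \code{NULL} for all.
#' @return list with \code{percent_immobile}, \code{percent_mobile} (summing
#'   to 100 over classified tracks), \code{n_classified},
#'   \code{n_unclassified}, and \code{per_track} (track_id, duration,
#'   spread_px, class).
#' @export
classify_mobility <- function(tracks, precision_px = 0.2,
                              min_immobile_frames = 10,
                              min_mobile_frames = 5,
                              spread_mult = 2, step_mult = 4,
                              first_n_frames = NULL) {
  stopifnot(precision_px > 0,
            all(c("track_id", "frame", "x_px", "y_px") %in% names(tracks)))
  if (!is.null(first_n_frames))
    tracks <- tracks[tracks$frame <= min(tracks$frame, na.rm = TRUE) +
                       first_n_frames - 1, , drop = FALSE]
  per <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    dur <- nrow(tr)
    spread <- sqrt(mean((tr$x_px - mean(tr$x_px))^2 +
                          (tr$y_px - mean(tr$y_px))^2))
    cls <- "unclassified"
    if (dur >= min_immobile_frames && spread <= spread_mult * precision_px) {
      cls <- "immobile"
    } else if (dur >= 2) {
      steps <- sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)
      big <- steps > step_mult * precision_px
      runs <- rle(big)
      if (any(runs$values & runs$lengths >= min_mobile_frames))
        cls <- "mobile"
    }
    data.frame(track_id = tr$track_id[1], duration = dur,
               spread_px = spread, class = cls, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_imm <- sum(per$class == "immobile")
  n_mob <- sum(per$class == "mobile")
  n_cls <- n_imm + n_mob
  if (n_cls == 0) stop("no classifiable tracks")
  list(percent_immobile = 100 * n_imm / n_cls,
       percent_mobile = 100 * n_mob / n_cls,
       n_classified = n_cls,
       n_unclassified = sum(per$class == "unclassified"),
       per_track = per)
}

#' Write tracks as CSV (track_id, frame, x_px, y_px)
#' @param tracks track data.frame from \code{\link{link_tracks}}.
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks[, c("track_id", "frame", "x_px", "y_px")],
                   path, row.names = FALSE)
  invisible(path)
}
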