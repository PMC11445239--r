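#' Calcein-release time series from a liposome leakage assay
#'
#' Validates and bundles one well's fluorescence channels: the sample trace,
#' the liposome-only (intact) reference and the per-well maximum fluorescence
#' after detergent solubilization.
#'
#' @param time_min strictly increasing time points, minutes.
#' @param f_sample sample fluorescence trace (a.u.), one value per time point.
#' @param f_only_luvs liposome-only fluorescence (a.u.); scalar or per-time.
#' @param f_triton per-well maximum fluorescence after Triton addition (a.u.),
#'   scalar.
#' @return An object of class \code{leakage_series}. If
#'   \code{f_triton <= f_only_luvs} the well is marked invalid
#'   (\code{valid = FALSE}) and cannot be scored.
#' @export
leakage_series <- function(time_min, f_sample, f_only_luvs, f_triton) {
  stopifnot(is.numeric(time_min), length(time_min) >= 1,
            all(diff(time_min) > 0),
            length(f_sample) == length(time_min),
            length(f_triton) == 1,
            length(f_only_luvs) %in% c(1, length(time_min)))
  valid <- all(f_triton > f_only_luvs)
  structure(list(time_min = time_min, f_sample = f_sample,
                 f_only_luvs = f_only_luvs, f_triton = f_triton,
                 valid = valid),
            class = "leakage_series")
}

#' Percent calcein release
#'
#' Applies, per time point,
#' \deqn{\%release = 100 \times \frac{F_{sample} - F_{onlyLUVs}}
#'                               {F_{Triton} - F_{onlyLUVs}}.}
#' Values outside [0, 100] can arise through measurement noise; they are
#' reported unclamped and flagged in the \code{out_of_range} column.
#'
#' @param ts a \code{\link{leakage_series}}.
#' @return data.frame with \code{time_min}, \code{release_percent},
#'   \code{out_of_range}.
#' @export
calcein_release <- function(ts) {
  stopifnot(inherits(ts, "leakage_series"))
  if (!ts$valid)
    stop("invalid well: F_triton must exceed F_only_luvs")
  rel <- 100 * (ts$f_sample - ts$f_only_luvs) / (ts$f_triton - ts$f_only_luvs)
  data.frame(time_min = ts$time_min,
             release_percent = rel,
             out_of_range = rel < 0 | rel > 100)
}

#' Liposome preparation quality check
#'
#' A liposome fraction passes when the ratio of permeabilized to intact
#' fluorescence is at least \code{min_ratio} (default 5), i.e. the encapsulated
#' calcein is sufficiently self-quenched.
#'
#' @param f_permeabilized fluorescence after full permeabilization (a.u., > 0).
#' @param f_intact fluorescence of the intact liposomes (a.u., > 0).
#' @param min_ratio minimum acceptable ratio.
#' @return logical: \code{TRUE} when the fraction passes.
#' @export
leakage_quality_check <- function(f_permeabilized, f_intact, min_ratio = 5) {
  if (any(f_permeabilized <= 0) || any(f_intact <= 0))
    stop("fluorescence values must be positive")
  f_permeabilized / f_intact >= min_ratio
}

#' Score a long-format leakage plate CSV
#'
#' Expects columns \code{well}, \code{time_min}, \code{channel}, \code{value},
#' with channels \code{sample}, \code{only_luvs} and \code{triton} (triton:
#' one value per well, its maximum is used). Returns per-well release traces;
#' invalid wells (triton <= only_luvs) are skipped with a warning.
#'
#' @param df long-format data.frame (or path to a CSV file).
#' @return data.frame with \code{well}, \code{time_min},
#'   \code{release_percent}, \code{out_of_range}.
#' @export
score_leakage_plate <- function(df) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  stopifnot(all(c("well", "time_min", "channel", "value") %in% names(df)))
  out <- lapply(split(df, df$well), function(w) {
    smp <- w[w$channel == "sample", ]
    smp <- smp[order(smp$time_min), ]
    bg <- w$value[w$channel == "only_luvs"]
    tri <- max(w$value[w$channel == "triton"])
    bg <- if (length(bg) == nrow(smp)) bg[order(w$time_min[w$channel == "only_luvs"])]
          else mean(bg)
    ts <- tryCatch(leakage_series(smp$time_min, smp$value, bg, tri),
                   error = function(e) NULL)
    if (is.null(ts) || !ts$valid) {
      warning(sprintf("well %s invalid (F_triton <= F_only_luvs); skipped",
                      w$well[1]))
      return(NULL)
    }
    cbind(well = w$well[1], calcein_release(ts))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
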