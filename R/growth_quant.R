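#' Maximum-slope growth rate of an OD curve
#'
#' The growth rate is the maximum over all windows of \code{window}
#' consecutive points of the least-squares slope of OD against time
#' (OD units per hour). Negative maxima are clipped to 0.
#'
#' @param time time points in hours, strictly increasing, >= 4 points.
#' @param od OD600 readings, same length.
#' @param window number of consecutive points per regression window,
#'   >= 3 and <= length(time). Default 5.
#' @return maximum slope (OD/h), >= 0.
#' @export
max_slope_rate <- function(time, od, window = 5L) {
  n <- length(time)
  if (n < 4L) stop("growth curve needs at least 4 time points")
  if (length(od) != n) stop("time and od lengths differ")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  if (window < 3L || window > n) stop("window must be in [3, n points]")
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    t <- time[idx]; y <- od[idx]
    tc <- t - mean(t)
    sum(tc * y) / sum(tc^2)
  }, numeric(1))
  max(0, max(slopes))
}

#' Endpoint of a growth curve
#'
#' Final OD minus initial OD, a proxy for saturation. A negative endpoint
#' (monotone-decreasing curve) is reported as-is with a warning.
#'
#' @param od OD600 readings in time order (>= 2 points).
#' @return OD difference.
#' @export
endpoint <- function(od) {
  if (length(od) < 2L) stop("endpoint needs at least 2 readings")
  e <- od[length(od)] - od[1L]
  if (e < 0) warning("negative endpoint (OD decreased over the curve)")
  e
}

#' Replicate voting and summary for one species x carbon source
#'
#' A replicate "grew" if its endpoint reaches \code{grow_threshold}; the
#' species grows iff at least \code{min_grow} replicates grew (the 2-of-3
#' rule by default). When the species does not grow, rate and endpoint are
#' set to 0; otherwise they are replicate means.
#'
#' @param reps data frame with columns rate and endpoint, one row per
#'   replicate.
#' @param min_grow minimum number of growing replicates (default 2).
#' @param grow_threshold endpoint OD defining "grew" (default 0.2).
#' @return list: grows, rate (mean), endpoint (mean), n_grew, n_reps.
#' @export
replicate_call <- function(reps, min_grow = 2L, grow_threshold = 0.2) {
  if (nrow(reps) < 1L) stop("no replicates")
  grew <- reps$endpoint >= grow_threshold
  grows <- sum(grew) >= min_grow
  list(grows = grows,
       rate = if (grows) mean(reps$rate) else 0,
       endpoint = if (grows) mean(reps$endpoint) else 0,
       n_grew = sum(grew), n_reps = nrow(reps))
}

#' Normalize a growth rate to the glucose control
#'
#' Reported as test mean rate / control mean rate so that 1 means the
#' species grew equally fast on both carbon sources. Replicate means are
#' rounded to 3 decimals before the ratio and the reported ratio to 2
#' decimals (reproducing standard printed tables); the full-precision ratio
#' is retained alongside. A non-growing test gives 0; a non-growing control
#' flags the result undefined.
#'
#' @param test \code{replicate_call} result for the test carbon source.
#' @param control \code{replicate_call} result for the glucose control.
#' @return list: ratio (full precision), ratio_reported (rounding ladder),
#'   undefined flag.
#' @export
normalize_to_control <- function(test, control) {
  if (!isTRUE(control$grows) || control$rate <= 0)
    return(list(ratio = NA_real_, ratio_reported = NA_real_,
                undefined = TRUE))
  if (!isTRUE(test$grows))
    return(list(ratio = 0, ratio_reported = 0, undefined = FALSE))
  list(ratio = test$rate / control$rate,
       ratio_reported = round(round(test$rate, 3) / round(control$rate, 3), 2),
       undefined = FALSE)
}

#' Quantify a long-format growth-curve table
#'
#' Runs the full growth pipeline: per-replicate maximum-slope rate and
#' endpoint, replicate voting per species x carbon source, and
#' normalization of every non-control source to the glucose control.
#'
#' @param curves data frame with columns species, source, replicate,
#'   time_h, od.
#' @param control carbon source used as control (default "glucose").
#' @param window,min_grow,grow_threshold see \code{max_slope_rate} and
#'   \code{replicate_call}.
#' @return data frame with one row per species x source: grows, rate,
#'   endpoint, n_grew, normalized (vs control, full precision),
#'   normalized_reported.
#' @export
quantify_growth <- function(curves, control = "glucose", window = 5L,
                            min_grow = 2L, grow_threshold = 0.2) {
  per_rep <- do.call(rbind, lapply(
    split(curves, list(curves$species, curves$source, curves$replicate),
          drop = TRUE),
    function(d) {
      d <- d[order(d$time_h), ]
      data.frame(species = d$species[1L], source = d$source[1L],
                 replicate = d$replicate[1L],
                 rate = max_slope_rate(d$time_h, d$od, window),
                 endpoint = endpoint(d$od), stringsAsFactors = FALSE)
    }))
  calls <- lapply(split(per_rep, list(per_rep$species, per_rep$source),
                        drop = TRUE),
                  function(d) c(list(species = d$species[1L],
                                     source = d$source[1L]),
                                replicate_call(d, min_grow, grow_threshold)))
  out <- do.call(rbind, lapply(calls, function(x)
    data.frame(species = x$species, source = x$source, grows = x$grows,
               rate = x$rate, endpoint = x$endpoint, n_grew = x$n_grew,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out$normalized <- NA_real_
  out$normalized_reported <- NA_real_
  for (sp in unique(out$species)) {
    ctrl_row <- which(out$species == sp & out$source == control)
    if (length(ctrl_row) != 1L) next
    ctrl <- as.list(out[ctrl_row, ])
    for (i in which(out$species == sp & out$source != control)) {
      nm <- normalize_to_control(as.list(out[i, ]), ctrl)
      out$normalized[i] <- nm$ratio
      out$normalized_reported[i] <- nm$ratio_reported
    }
  }
  out
}
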