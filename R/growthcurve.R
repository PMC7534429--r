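#' Maximal growth rate from an OD time series
#'
#' Slides a window of `window_hours` along the blank-corrected curve,
#' stepping by one sampling interval, and fits a least-squares regression of
#' `ln(OD - blank)` on time within each window (endpoints inclusive). The
#' maximal growth rate is the largest window slope — the Malthusian rate of
#' the fastest phase. Windows containing non-positive blank-corrected OD are
#' skipped; they invalidate only themselves, not the series.
#'
#' @param series data.frame with columns `time_h` and `od` (e.g. from
#'   [simulate_growth_curve()]); timestamps must be strictly increasing.
#' @param window_hours window length in hours (default 7).
#' @param blank additive blank OD to subtract; defaults to the series'
#'   `"blank"` attribute, else 0.
#' @return list: `rate` (per hour), `window_start` (hours), `r_squared`,
#'   `n_windows` evaluated.
#' @export
max_growth_rate <- function(series, window_hours = 7, blank = NULL) {
  stopifnot(is.data.frame(series), all(c("time_h", "od") %in% names(series)))
  t <- series$time_h
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(blank)) blank <- attr(series, "blank")
  if (is.null(blank)) blank <- 0
  y <- series$od - blank
  span <- t[length(t)] - t[1]
  if (span < window_hours) stop("series shorter than the window")
  best <- list(rate = -Inf, window_start = NA_real_, r_squared = NA_real_)
  n_windows <- 0L
  for (i in seq_along(t)) {
    j <- which(t >= t[i] & t <= t[i] + window_hours + 1e-9)
    if (t[max(j)] - t[i] < window_hours - 1e-9) break
    n_windows <- n_windows + 1L
    yw <- y[j]
    if (any(yw <= 0)) next
    tw <- t[j]
    ly <- log(yw)
    tc <- tw - mean(tw)
    sxx <- sum(tc^2)
    slope <- sum(tc * ly) / sxx
    if (slope > best$rate) {
      fit <- mean(ly) + slope * tc
      ss_res <- sum((ly - fit)^2)
      ss_tot <- sum((ly - mean(ly))^2)
      best <- list(rate = slope, window_start = tw[1],
                   r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
    }
  }
  if (!is.finite(best$rate)) {
    stop("no window with all blank-corrected OD > 0")
  }
  c(best, list(n_windows = n_windows))
}

#' Ancestor-referenced plate position correction
#'
#' Removes additive plate effects by subtracting, from every value on a
#' plate, the deviation of that plate's ancestor controls from the grand
#' ancestor mean. The corrected ancestor grand mean is unchanged by
#' construction. With `covariate` supplied (e.g. culture density for
#' sporulation assays), its effect is first removed by an
#' ancestor-referenced linear adjustment: a regression of the ancestor
#' controls on the covariate is subtracted from all values (centered on the
#' ancestor covariate mean) before the plate correction.
#'
#' @param values numeric vector of trait values.
#' @param plate plate identifier per value.
#' @param is_ancestor logical per value; every plate needs >= 1 control.
#' @param covariate optional numeric covariate per value.
#' @return numeric vector of corrected values.
#' @export
correct_position_effects <- function(values, plate, is_ancestor,
                                     covariate = NULL) {
  stopifnot(length(values) == length(plate),
            length(values) == length(is_ancestor))
  is_ancestor <- as.logical(is_ancestor)
  if (!is.null(covariate)) {
    fit <- stats::lm(values[is_ancestor] ~ covariate[is_ancestor])
    b <- stats::coef(fit)[2]
    if (is.finite(b)) {
      values <- values - b * (covariate - mean(covariate[is_ancestor]))
    }
  }
  plate <- as.character(plate)
  anc_by_plate <- tapply(values[is_ancestor], plate[is_ancestor], mean)
  missing <- setdiff(unique(plate), names(anc_by_plate))
  if (length(missing) > 0) {
    stop("plate(s) without ancestor controls: ",
         paste(missing, collapse = ", "))
  }
  grand <- mean(values[is_ancestor])
  unname(values - as.numeric(anc_by_plate[plate] - grand))
}

#' Reduce a long-format plate-reader table to maximal growth rates
#'
#' @param df data.frame with columns `plate`, `well`, `time_h`, `od`.
#' @param window_hours sliding-window length (hours).
#' @param blank additive blank OD (single value applied to all wells).
#' @return data.frame with one row per (plate, well): `rate`,
#'   `window_start`, `r_squared`.
#' @export
reduce_growth_curves <- function(df, window_hours = 7, blank = 0) {
  stopifnot(all(c("plate", "well", "time_h", "od") %in% names(df)))
  key <- interaction(df$plate, df$well, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    fit <- max_growth_rate(d[, c("time_h", "od")], window_hours, blank)
    data.frame(plate = d$plate[1], well = d$well[1], rate = fit$rate,
               window_start = fit$window_start, r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
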