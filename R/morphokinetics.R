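# Morphokinetic features: event times, all pairwise intervals and ratios,
# and the distance-from-linear-regression (DLR) statistic.

#' Morphokinetic event catalog
#'
#' Event order used everywhere for pair enumeration: pronucleus appearance
#' (tPNa) and fading (tPNf), then cleavage to 2..8 blastomeres (t2..t8),
#' all in hours post-ICSI.
#'
#' @return character vector of the 9 event names in chronological catalog
#'   order.
#' @export
mk_events <- function() {
  c("tPNa", "tPNf", "t2", "t3", "t4", "t5", "t6", "t7", "t8")
}

# All C(9,2) = 36 unordered event pairs, earlier event first.
mk_event_pairs <- function() {
  ev <- mk_events()
  pairs <- utils::combn(ev, 2)
  data.frame(earlier = pairs[1, ], later = pairs[2, ],
             stringsAsFactors = FALSE)
}

#' Validate a morphokinetic profile
#'
#' Present values must be strictly positive and chronologically ordered
#' following the event catalog; any event may be missing.
#'
#' @param p named numeric vector or one-row data.frame with (a subset of)
#'   the [mk_events()] names.
#' @return named numeric vector of length 9 (missing events `NA`).
#' @export
mk_profile <- function(p) {
  ev <- mk_events()
  if (is.data.frame(p)) p <- unlist(p[1, intersect(names(p), ev)])
  out <- stats::setNames(rep(NA_real_, 9L), ev)
  out[intersect(names(p), ev)] <- as.numeric(p[intersect(names(p), ev)])
  pres <- out[!is.na(out)]
  if (any(pres <= 0)) stop("event times must be strictly positive")
  if (is.unsorted(pres, strictly = FALSE))
    stop("event times out of chronological order")
  out
}

#' Pairwise intervals and ratios between morphokinetic events
#'
#' For each of the 36 unordered event pairs in chronological catalog order,
#' emits the interval `t_later - t_earlier` and the ratio
#' `t_later / t_earlier`. A missing operand propagates to a missing output;
#' a zero earlier time yields a missing ratio (flagged).
#'
#' @param p a morphokinetic profile (see [mk_profile()]).
#' @return named numeric vector of 72 values (`int_<a>_<b>`, `ratio_<a>_<b>`),
#'   with a `flags` attribute listing degenerate ratios.
#' @export
pairwise_intervals_and_ratios <- function(p) {
  p <- mk_profile(p)
  pr <- mk_event_pairs()
  a <- p[pr$earlier]; b <- p[pr$later]
  ints <- stats::setNames(b - a, paste0("int_", pr$earlier, "_", pr$later))
  rats <- b / a
  flags <- character(0)
  zero <- !is.na(a) & a == 0
  if (any(zero)) {
    rats[zero] <- NA_real_
    flags <- paste0("zero-denominator ratio: ", pr$earlier[zero])
  }
  rats <- stats::setNames(rats, paste0("ratio_", pr$earlier, "_", pr$later))
  out <- c(ints, rats)
  attr(out, "flags") <- flags
  out
}

#' Fit the regression lines behind the DLR statistic
#'
#' Ordinary least-squares line `t_later = slope * t_earlier + intercept`
#' per event pair, fitted on live-birth embryos only (the statistic measures
#' deviation from the average profile of positively implanted LB embryos).
#' Pairs with fewer than two complete cases yield no line; a predictor with
#' zero variance is a degenerate pair.
#'
#' @param lb_profiles data.frame of LB-embryo event times (columns from
#'   [mk_events()]).
#' @return data.frame with one row per event pair: `earlier`, `later`,
#'   `slope`, `intercept`, `n_fit`, `r_squared`, `flag`.
#' @export
fit_dlr_lines <- function(lb_profiles) {
  pr <- mk_event_pairs()
  res <- pr
  res$slope <- res$intercept <- res$r_squared <- NA_real_
  res$n_fit <- 0L
  res$flag <- ""
  for (k in seq_len(nrow(pr))) {
    x <- lb_profiles[[pr$earlier[k]]]
    y <- lb_profiles[[pr$later[k]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    res$n_fit[k] <- n
    if (n < 2L) { res$flag[k] <- "insufficient cases"; next }
    x <- x[ok]; y <- y[ok]
    vx <- stats::var(x)
    if (vx == 0) { res$flag[k] <- "degenerate: zero predictor variance"; next }
    slope <- stats::cov(x, y) / vx
    intercept <- mean(y) - slope * mean(x)
    fitted <- slope * x + intercept
    sst <- sum((y - mean(y))^2)
    res$slope[k] <- slope
    res$intercept[k] <- intercept
    res$r_squared[k] <- if (sst == 0) 1 else 1 - sum((y - fitted)^2) / sst
  }
  res
}

#' Distance from linear regression (DLR)
#'
#' Unsigned shortest Euclidean distance of an embryo's point
#' `(t_earlier, t_later)` from the LB regression line of that event pair:
#' `|slope * t_e - t_l + intercept| / sqrt(slope^2 + 1)`. Zero iff the point
#' lies on the line. With `signed = TRUE` the perpendicular offset keeps its
#' side of the line (not part of the standard catalog).
#'
#' @param t_earlier,t_later event times in hours (either may be `NA`).
#' @param line one row of [fit_dlr_lines()] output (or any list with
#'   `slope`, `intercept`).
#' @param signed keep the sign of the offset? Default `FALSE`.
#' @return distance in hours, `NA` if an event is missing or no line exists.
#' @export
dlr <- function(t_earlier, t_later, line, signed = FALSE) {
  slope <- line$slope; intercept <- line$intercept
  d <- (slope * t_earlier - t_later + intercept) / sqrt(slope^2 + 1)
  if (!signed) d <- abs(d)
  d
}

# The 117 morphokinetic feature columns for one profile: 9 events + 36
# intervals + 36 ratios + 36 DLR values (lines supplied by the caller).
morphokinetics_catalog <- function(p, lines) {
  p <- mk_profile(p)
  ir <- pairwise_intervals_and_ratios(p)
  dl <- rep(NA_real_, nrow(lines))
  for (k in seq_len(nrow(lines))) {
    if (is.na(lines$slope[k])) next
    dl[k] <- dlr(p[[lines$earlier[k]]], p[[lines$later[k]]], lines[k, ])
  }
  names(dl) <- paste0("dlr_", lines$earlier, "_", lines$later)
  c(p, ir, dl)
}

morphokinetics_feature_names <- function() {
  pr <- mk_event_pairs()
  c(mk_events(),
    paste0("int_", pr$earlier, "_", pr$later),
    paste0("ratio_", pr$earlier, "_", pr$later),
    paste0("dlr_", pr$earlier, "_", pr$later))
}
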