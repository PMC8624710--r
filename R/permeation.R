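#' Dilution-corrected cumulative permeation profile
#'
#' Converts a receptor-phase concentration series into the cumulative amount
#' permeated per unit membrane area, correcting for the sample volume
#' withdrawn and replaced with fresh buffer at every timepoint:
#' \deqn{Q_n = (c_n V_{receptor} + V_{sample} \sum_{i<n} c_i) / area}
#'
#' @param raw A \code{raw_series} data.frame (columns \code{time_h},
#'   \code{conc_ug_per_ml}, plus \code{cell_id/compound/membrane} labels).
#' @param cell A \code{\link{cell_config}}.
#' @return data.frame of class \code{permeation_profile} with columns
#'   \code{cell_id, compound, membrane, time_h, Q_ug_per_cm2}.
#' @export
cumulative_amount <- function(raw, cell) {
  stopifnot(inherits(cell, "cell_config"))
  if (is.null(raw$time_h) || is.null(raw$conc_ug_per_ml))
    stop("raw series needs time_h and conc_ug_per_ml columns")
  conc <- raw$conc_ug_per_ml
  if (length(conc) != length(raw$time_h))
    stop("misaligned concentration/time lengths")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  if (any(diff(raw$time_h) <= 0)) stop("times must be strictly increasing")
  prior <- c(0, cumsum(conc)[-length(conc)])
  q <- (conc * cell$V_receptor + cell$V_sample * prior) / cell$area
  out <- data.frame(
    cell_id = if (is.null(raw$cell_id)) "cell1" else raw$cell_id,
    compound = if (is.null(raw$compound)) NA_character_ else raw$compound,
    membrane = if (is.null(raw$membrane)) NA_character_ else raw$membrane,
    time_h = raw$time_h, Q_ug_per_cm2 = q, stringsAsFactors = FALSE)
  class(out) <- c("permeation_profile", "data.frame")
  out
}

#' Per-interval permeation rate
#'
#' Finite-difference rate between consecutive sampling times, with the
#' origin (Q = 0 at t = 0) prepended.
#'
#' @param profile A \code{permeation_profile}.
#' @return data.frame with \code{t_start, t_end, rate_ug_per_cm2_h}.
#' @export
interval_flux <- function(profile) {
  t <- profile$time_h
  q <- profile$Q_ug_per_cm2
  if (length(t) < 2L) stop("need at least 2 timepoints")
  if (anyDuplicated(t) || any(diff(t) <= 0))
    stop("duplicate or non-increasing times")
  t0 <- c(0, t)
  q0 <- c(0, q)
  data.frame(t_start = t0[-length(t0)], t_end = t,
             rate_ug_per_cm2_h = diff(q0) / diff(t0))
}

# fast OLS of q on t over an index window; returns slope/intercept/r2
.window_ols <- function(t, q, s, e) {
  ti <- t[s:e]; qi <- q[s:e]
  mt <- mean(ti); mq <- mean(qi)
  sxx <- sum((ti - mt)^2)
  sxy <- sum((ti - mt) * (qi - mq))
  slope <- sxy / sxx
  intercept <- mq - slope * mt
  sst <- sum((qi - mq)^2)
  sse <- sum((qi - intercept - slope * ti)^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Fit the steady-state regime of a permeation profile
#'
#' Ordinary least squares of cumulative amount on time over a selected
#' contiguous window of sampling points. The default window strategy
#' searches all contiguous windows of at least \code{min_points} points with
#' positive slope and keeps the one maximizing the coefficient of
#' determination r^2; ties are broken by longer window, then earlier start.
#' Alternatively \code{strategy = "last_points"} fits the final
#' \code{min_points} points.
#'
#' @param profile A \code{permeation_profile}.
#' @param cell A \code{\link{cell_config}} (supplies \code{C_donor} for the
#'   permeability coefficient).
#' @param strategy Window-selection rule, \code{"max_r2"} (default) or
#'   \code{"last_points"}.
#' @param min_points Minimum window width (>= 4).
#' @return List of class \code{steady_state_fit}: \code{J_ss} (slope,
#'   ug cm^-2 h^-1), \code{intercept}, \code{L_T} (x-intercept, h),
#'   \code{K_p} (= J_ss / C_donor, cm/h), \code{r2_fit}, \code{window}
#'   (start/end indices) and the labels of the profile.
#' @export
fit_steady_state <- function(profile, cell,
                             strategy = c("max_r2", "last_points"),
                             min_points = 4L) {
  stopifnot(inherits(cell, "cell_config"))
  strategy <- match.arg(strategy)
  t <- profile$time_h
  q <- profile$Q_ug_per_cm2
  n <- length(t)
  if (n < min_points) stop("need at least ", min_points, " timepoints")
  if (min_points < 4L) stop("min_points must be >= 4")
  best <- NULL
  if (strategy == "last_points") {
    s <- n - min_points + 1L
    f <- .window_ols(t, q, s, n)
    if (f$slope <= 0) stop("no steady state: slope <= 0 in terminal window")
    best <- c(f, list(s = s, e = n))
  } else {
    for (s in seq_len(n - min_points + 1L)) {
      for (e in seq.int(s + min_points - 1L, n)) {
        f <- .window_ols(t, q, s, e)
        if (!is.finite(f$slope) || f$slope <= 0 || !is.finite(f$r2)) next
        cand <- c(f, list(s = s, e = e))
        if (is.null(best) ||
            f$r2 > best$r2 ||
            (f$r2 == best$r2 && (e - s) > (best$e - best$s)) ||
            (f$r2 == best$r2 && (e - s) == (best$e - best$s) && s < best$s)) {
          best <- cand
        }
      }
    }
    if (is.null(best))
      stop("no steady state: slope <= 0 in every candidate window")
  }
  lt <- -best$intercept / best$slope
  if (lt < 0)
    warning("negative fitted lag time (", signif(lt, 3),
            " h); reported as-is")
  structure(list(
    cell_id = profile$cell_id[1], compound = profile$compound[1],
    membrane = profile$membrane[1],
    J_ss = best$slope, intercept = best$intercept, L_T = lt,
    K_p = best$slope / cell$C_donor, r2_fit = best$r2,
    window = c(start = best$s, end = best$e)), class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf(
    "steady_state_fit [%s | %s | %s]\n  J_ss = %.2f ug/cm^2/h, L_T = %.2f h, K_p*10^3 = %.2f cm/h, r2 = %.4f (points %d-%d)\n",
    x$cell_id, x$compound, x$membrane, x$J_ss, x$L_T, 1000 * x$K_p,
    x$r2_fit, x$window[1], x$window[2]))
  invisible(x)
}

#' Permeability coefficient from flux and donor concentration
#'
#' @param J_ss Steady-state flux, ug cm^-2 h^-1.
#' @param C_donor Donor concentration, ug/cm^3.
#' @return K_p = J_ss / C_donor, cm/h.
#' @export
permeability_coefficient <- function(J_ss, C_donor) {
  if (!is.finite(C_donor) || C_donor <= 0) stop("C_donor must be positive")
  J_ss / C_donor
}

#' Aggregate per-cell fits into a compound summary
#'
#' Arithmetic mean and sample SD (n - 1 denominator) over replicate cells of
#' J_ss, K_p*10^3 and L_T, plus the 24 h (final-timepoint) cumulative mass
#' from the matching profiles. All fits must share one compound x membrane.
#'
#' @param fits List of \code{steady_state_fit} objects.
#' @param profiles Optional list of the matching \code{permeation_profile}s
#'   (for the final-timepoint cumulative mass).
#' @return One-row data.frame of class \code{compound_summary}.
#' @export
aggregate_cells <- function(fits, profiles = NULL) {
  if (length(fits) < 1L) stop("need at least one fit")
  cmp <- unique(vapply(fits, `[[`, character(1), "compound"))
  mem <- unique(vapply(fits, `[[`, character(1), "membrane"))
  if (length(cmp) > 1L || length(mem) > 1L)
    stop("mixed compounds/membranes in one group: ",
         paste(cmp, collapse = ","), " / ", paste(mem, collapse = ","))
  jss <- vapply(fits, `[[`, numeric(1), "J_ss")
  kpe3 <- 1000 * vapply(fits, `[[`, numeric(1), "K_p")
  lt <- vapply(fits, `[[`, numeric(1), "L_T")
  sd_or_na <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  q24_mean <- NA_real_; q24_sd <- NA_real_
  if (!is.null(profiles)) {
    q24 <- vapply(profiles, function(p) p$Q_ug_per_cm2[nrow(p)], numeric(1))
    q24_mean <- mean(q24); q24_sd <- sd_or_na(q24)
  }
  out <- data.frame(
    compound = cmp, membrane = mem, n = length(fits),
    Jss_mean = mean(jss), Jss_sd = sd_or_na(jss),
    Kp_e3_mean = mean(kpe3), Kp_e3_sd = sd_or_na(kpe3),
    LT_mean = mean(lt), LT_sd = sd_or_na(lt),
    Q24_mean = q24_mean, Q24_sd = q24_sd, stringsAsFactors = FALSE)
  class(out) <- c("compound_summary", "data.frame")
  out
}

#' Inter-membrane permeation ratio
#'
#' Ratio of mean steady-state fluxes between two membranes for the same
#' compound (conventionally Strat-M over skin). Accepts either
#' \code{compound_summary} rows or bare numeric mean fluxes. The returned
#' value is unrounded; reports round to 2 decimal places.
#'
#' @param summary_a Numerator summary (or numeric mean flux).
#' @param summary_b Denominator summary (or numeric mean flux).
#' @return Dimensionless flux ratio.
#' @export
permeation_ratio <- function(summary_a, summary_b) {
  ja <- if (is.numeric(summary_a)) summary_a else summary_a$Jss_mean
  jb <- if (is.numeric(summary_b)) summary_b else summary_b$Jss_mean
  if (!is.numeric(summary_a) && !is.numeric(summary_b) &&
      !identical(summary_a$compound, summary_b$compound))
    stop("permeation ratio requires the same compound on both membranes")
  if (any(jb == 0)) stop("zero denominator flux")
  ja / jb
}

#' Analyze a long-format study dataset
#'
#' Runs the per-cell pipeline (dilution correction, steady-state fit) over
#' every cell in a long-format dataset and aggregates replicates per
#' compound x membrane.
#'
#' @param data Long-format data.frame with columns
#'   \code{cell_id, compound, membrane, time_h, conc_ug_per_ml}.
#' @param cell A \code{\link{cell_config}}.
#' @param strategy,min_points Passed to \code{\link{fit_steady_state}}.
#' @return List with \code{profiles} (per-cell \code{permeation_profile}s),
#'   \code{fits} (per-cell \code{steady_state_fit}s) and \code{summaries}
#'   (data.frame, one row per compound x membrane).
#' @export
analyze_study <- function(data, cell = cell_config(),
                          strategy = "max_r2", min_points = 4L) {
  needed <- c("cell_id", "compound", "membrane", "time_h", "conc_ug_per_ml")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0L)
    stop("dataset is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(data) == 0L) stop("empty dataset")
  key <- interaction(data$compound, data$membrane, data$cell_id, drop = TRUE)
  cells <- split(data, key)
  profiles <- lapply(cells, function(d) {
    d <- d[order(d$time_h), ]
    cumulative_amount(d, cell)
  })
  fits <- lapply(profiles, fit_steady_state, cell = cell,
                 strategy = strategy, min_points = min_points)
  gkey <- vapply(fits, function(f) paste(f$compound, f$membrane, sep = "|"),
                 character(1))
  summaries <- do.call(rbind, lapply(split(seq_along(fits), gkey), function(i)
    aggregate_cells(fits[i], profiles[i])))
  rownames(summaries) <- NULL
  list(profiles = profiles, fits = fits, summaries = summaries)
}
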