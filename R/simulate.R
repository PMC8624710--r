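#' Franz-cell geometry and dosing configuration
#'
#' @param area Diffusion area in contact with the membrane, cm^2.
#' @param V_receptor Receptor-chamber volume, mL.
#' @param V_sample Volume withdrawn (and replaced with fresh buffer) at each
#'   sampling time, mL.
#' @param C_donor Donor-phase active concentration, ug/cm^3 (= ug/mL). The
#'   default corresponds to a 5 percent w/w cream at unit density.
#' @return List of class \code{cell_config}.
#' @export
cell_config <- function(area = 1, V_receptor = 8, V_sample = 0.5,
                        C_donor = 50000) {
  if (!all(is.finite(c(area, V_receptor, V_sample, C_donor))))
    stop("cell_config fields must be finite numbers")
  if (area <= 0 || C_donor <= 0) stop("area and C_donor must be positive")
  if (V_sample <= 0 || V_sample >= V_receptor)
    stop("need 0 < V_sample < V_receptor")
  structure(list(area = area, V_receptor = V_receptor, V_sample = V_sample,
                 C_donor = C_donor), class = "cell_config")
}

#' Sampling schedule
#'
#' @param times Strictly increasing sampling times, h; first time must be
#'   positive. The default is dense around the 3-5 h permeation-rate peak
#'   and ends at 24 h.
#' @return Numeric vector of class \code{sampling_schedule}.
#' @export
sampling_schedule <- function(times = c(0.5, 1, 2, 3, 4, 5, 8, 24)) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)))
    stop("times must be finite")
  if (times[1] <= 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start after 0")
  structure(times, class = c("sampling_schedule", "numeric"))
}

#' Default membrane ground-truth panel
#'
#' One (kp, lt) pair per compound x membrane, taken from literature
#' steady-state kinetics for ibuprofen ion pairs through excised human skin
#' and the Strat-M synthetic membrane. Thickness is fixed per membrane
#' (dermatomed skin 0.05 cm, Strat-M 0.03 cm) and D, K are back-solved.
#'
#' @param registry A \code{compound_registry}; panel rows are restricted to
#'   its acronyms.
#' @param membranes Character vector of membrane labels to include.
#' @return data.frame with columns \code{acronym, membrane, kp, lt, D, h, K}.
#' @export
default_membrane_panel <- function(registry = default_compound_registry(),
                                   membranes = c("skin", "strat-m")) {
  ref <- utils::read.csv(
    system.file("extdata", "reference_kinetics.csv", package = "franzperm",
      mustWork = TRUE),
    stringsAsFactors = FALSE)
  ref <- ref[ref$acronym %in% registry$acronym & ref$membrane %in% membranes, ]
  if (nrow(ref) == 0L) stop("no panel rows match registry/membranes")
  h_by_membrane <- c("skin" = 0.05, "strat-m" = 0.03)
  panel <- data.frame(
    acronym = ref$acronym,
    membrane = ref$membrane,
    kp = ref$Kp_e3_mean / 1000,
    lt = ref$LT_mean,
    h = unname(h_by_membrane[ref$membrane]),
    stringsAsFactors = FALSE)
  if (anyNA(panel$h)) {
    panel$h[is.na(panel$h)] <- 0.03
  }
  panel$D <- panel$h^2 / (6 * panel$lt)
  panel$K <- panel$kp * panel$h / panel$D
  panel
}

#' Simulate one Franz-cell concentration series
#'
#' Emulates the withdrawal/replacement sampling protocol on top of the
#' analytic diffusion-lag solution. Receptor mass bookkeeping before sample
#' n is \code{m_n = area * Q(t_n) - V_sample * sum(measured c_i, i < n)};
#' the measured concentration is the true concentration \code{m_n /
#' V_receptor} perturbed by multiplicative Gaussian noise truncated at zero.
#' Withdrawal sums intentionally use the *measured* concentrations so that
#' the dilution correction in \code{\link{cumulative_amount}} inverts the
#' sampling model exactly.
#'
#' @param model A \code{\link{membrane_model}}.
#' @param cell A \code{\link{cell_config}}.
#' @param schedule A \code{\link{sampling_schedule}}.
#' @param noise_cv Assay coefficient of variation (fraction, >= 0).
#' @param seed Optional integer; when given the series is deterministic.
#'   When NULL the current RNG stream is used (as in
#'   \code{\link{generate_study}}).
#' @param cell_id,compound,membrane Labels copied into the output.
#' @return data.frame (class \code{raw_series}) with columns
#'   \code{cell_id, compound, membrane, time_h, conc_ug_per_ml}.
#' @export
simulate_sampling <- function(model, cell, schedule, noise_cv = 0.05,
                              seed = NULL, cell_id = "cell1",
                              compound = NA_character_,
                              membrane = NA_character_) {
  stopifnot(inherits(model, "membrane_model"), inherits(cell, "cell_config"))
  schedule <- sampling_schedule(unclass(schedule))
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  qt <- cumulative_permeation(model, cell$C_donor, as.numeric(schedule))
  n <- length(schedule)
  meas <- numeric(n)
  removed <- 0
  eps <- if (noise_cv > 0) stats::rnorm(n, 0, noise_cv) else numeric(n)
  for (i in seq_len(n)) {
    m_i <- cell$area * qt[i] - cell$V_sample * removed
    c_true <- m_i / cell$V_receptor
    meas[i] <- max(0, c_true * (1 + eps[i]))
    removed <- removed + meas[i]
  }
  out <- data.frame(cell_id = cell_id, compound = compound,
                    membrane = membrane, time_h = as.numeric(schedule),
                    conc_ug_per_ml = meas, stringsAsFactors = FALSE)
  class(out) <- c("raw_series", "data.frame")
  out
}

#' Simulate a full permeation study
#'
#' One series per compound x membrane x cell, with the generating membrane
#' model recorded alongside as ground truth for recovery tests.
#'
#' @param registry A \code{compound_registry}.
#' @param panel Ground-truth panel as returned by
#'   \code{\link{default_membrane_panel}}.
#' @param cell A \code{\link{cell_config}}.
#' @param schedule A \code{\link{sampling_schedule}}.
#' @param n_cells Replicate diffusion cells per formulation (default 3).
#' @param noise_cv Assay coefficient of variation.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return List with \code{data} (long-format data.frame:
#'   \code{cell_id, compound, membrane, time_h, conc_ug_per_ml}) and
#'   \code{truth} (the panel with derived \code{kp, lt} per row).
#' @export
generate_study <- function(registry = default_compound_registry(),
                           panel = default_membrane_panel(registry),
                           cell = cell_config(),
                           schedule = sampling_schedule(),
                           n_cells = 3, noise_cv = 0.05, seed = 1) {
  if (nrow(registry) == 0L) stop("registry is empty")
  if (n_cells < 1L) stop("n_cells must be >= 1")
  set.seed(seed)
  pieces <- vector("list", nrow(panel) * n_cells)
  idx <- 1L
  for (r in seq_len(nrow(panel))) {
    model <- membrane_model(D = panel$D[r], h = panel$h[r], K = panel$K[r])
    for (cc in seq_len(n_cells)) {
      pieces[[idx]] <- simulate_sampling(
        model, cell, schedule, noise_cv = noise_cv, seed = NULL,
        cell_id = sprintf("%s_%s_c%d", panel$acronym[r], panel$membrane[r], cc),
        compound = panel$acronym[r], membrane = panel$membrane[r])
      idx <- idx + 1L
    }
  }
  data <- do.call(rbind, pieces)
  rownames(data) <- NULL
  list(data = data, truth = panel)
}
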