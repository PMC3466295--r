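#' Total transpirable soil water from calibration pot weights
#'
#' TTSW is the plant-available water per pot: the difference between the
#' initial pot weight (field capacity after overnight drainage) and the final
#' pot weight (taken when stomatal conductance of the stressed calibration
#' plants has collapsed to 10\% of the well-watered controls).
#'
#' @param initial_weight initial pot weight (g).
#' @param final_weight final pot weight (g).
#' @return TTSW in grams.
#' @export
compute_ttsw <- function(initial_weight, final_weight) {
  stopifnot(is.numeric(initial_weight), is.numeric(final_weight))
  ttsw <- initial_weight - final_weight
  if (any(ttsw <= 0)) {
    stop("TTSW must be positive: initial pot weight must exceed final pot weight")
  }
  ttsw
}

#' Fraction of transpirable soil water along a pot-weight series
#'
#' FTSW on each day is (daily weight - final weight) / TTSW, clamped to
#' [0, 1]. Control plants have their transpired water restored daily, so
#' their FTSW is forced back to 1 every day.
#'
#' @param weight numeric vector of daily pot weights (g), on consecutive
#'   integer days starting at irrigation stop.
#' @param final_weight calibration final pot weight (g).
#' @param ttsw total transpirable soil water (g).
#' @param is_control logical; control plants are pinned at FTSW = 1.
#' @param day optional integer day indices; must be consecutive.
#' @return numeric vector of FTSW values, same length as \code{weight}.
#' @export
compute_ftsw_series <- function(weight, final_weight, ttsw,
                                is_control = FALSE, day = NULL) {
  if (ttsw <= 0) stop("ttsw must be positive")
  if (!is.null(day)) {
    if (any(diff(sort(day)) != 1L)) {
      stop("day gaps in pot-weight series; interpolation is not enabled")
    }
    weight <- weight[order(day)]
  }
  if (isTRUE(is_control)) return(rep(1, length(weight)))
  ftsw <- (weight - final_weight) / ttsw
  if (any(ftsw < -1e-12)) {
    warning("pot weight below calibration final weight; FTSW clamped to 0")
  }
  pmin(pmax(ftsw, 0), 1)
}

#' Integrated transpired water
#'
#' ITW accumulates the water deficit 1 - FTSW over the treatment period as a
#' daily rectangle sum, matching the daily weighing cadence. Under the
#' fixed-duration scenario it captures stress intensity at the common
#' harvest; under the fixed-intensity scenario it captures treatment
#' duration.
#'
#' @param ftsw numeric vector of daily FTSW values from irrigation stop
#'   through the day before harvest.
#' @return ITW (dimensionless days).
#' @export
compute_itw <- function(ftsw) {
  if (length(ftsw) == 0) {
    warning("empty FTSW range; ITW = 0")
    return(0)
  }
  sum(1 - ftsw)
}

#' Leaf relative water content
#'
#' RWC = (Fw - Dw) / (Tw - Dw) from fresh, turgid (24 h rehydration) and dry
#' (24 h at 80 C) leaf masses. Values slightly outside [0, 1] arise from
#' measurement noise and are kept (with a warning) unless \code{clamp}.
#'
#' @param Fw,Tw,Dw fresh, turgid and dry mass (g).
#' @param clamp clamp the result into [0, 1]?
#' @return RWC as a fraction.
#' @export
compute_rwc <- function(Fw, Tw, Dw, clamp = FALSE) {
  if (any(Tw <= Dw)) stop("turgid mass must exceed dry mass")
  rwc <- (Fw - Dw) / (Tw - Dw)
  out_of_range <- rwc < 0 | rwc > 1
  if (any(out_of_range)) {
    warning("RWC outside [0, 1] (measurement noise)")
    if (clamp) rwc <- pmin(pmax(rwc, 0), 1)
  }
  rwc
}

#' Leaf mass per area
#'
#' @param dry_mass disc dry mass (g).
#' @param area disc area (m^2).
#' @return LMA in g m^-2.
#' @export
compute_lma <- function(dry_mass, area) {
  if (any(area <= 0)) stop("disc area must be positive")
  dry_mass / area
}

#' Fixed-duration stress harvest day
#'
#' All plants of the fixed-duration blocks are harvested on the earliest day
#' on which at least half of the treated plants have FTSW below 0.35.
#'
#' @param ftsw_matrix treated-plant FTSW trajectories, days x plants (or a
#'   list of equal-length vectors).
#' @param threshold FTSW threshold (default 0.35).
#' @param fraction fraction of treated plants that must be below the
#'   threshold (default 0.5, read inclusively).
#' @param day0 day index of the first row (default 0 = irrigation stop).
#' @return harvest day index (single integer, shared by all plants).
#' @export
schedule_fds_harvest <- function(ftsw_matrix, threshold = 0.35,
                                 fraction = 0.5, day0 = 0L) {
  if (is.list(ftsw_matrix)) ftsw_matrix <- do.call(cbind, ftsw_matrix)
  ftsw_matrix <- as.matrix(ftsw_matrix)
  if (ncol(ftsw_matrix) < 1) stop("need at least one treated plant")
  frac_below <- rowMeans(ftsw_matrix < threshold)
  hit <- which(frac_below >= fraction)
  if (length(hit) == 0) {
    stop(sprintf(
      "FDS criterion never met: last-day fraction below %.2f is %.2f",
      threshold, frac_below[length(frac_below)]
    ))
  }
  as.integer(day0 + hit[1] - 1L)
}

#' Fixed-intensity stress harvest days
#'
#' Each treated plant is harvested on the earliest day its FTSW falls
#' strictly below 0.1; its paired control is harvested the same day.
#'
#' @param ftsw numeric vector, one treated plant's FTSW trajectory.
#' @param threshold FTSW threshold (default 0.1).
#' @param day0 day index of the first entry.
#' @return the plant's harvest day index.
#' @export
schedule_fis_harvest <- function(ftsw, threshold = 0.1, day0 = 0L) {
  hit <- which(ftsw < threshold)
  if (length(hit) == 0) {
    stop(sprintf("FIS criterion never met: trajectory never crosses FTSW < %.2f", threshold))
  }
  as.integer(day0 + hit[1] - 1L)
}

#' Derive per-plant phenostatistics from a pot-weight table
#'
#' Computes the FTSW trajectory and ITW for every plant in a long-format
#' pot-weight table (columns plant_id, day, weight_g, water_added_g), given
#' per-plant metadata.
#'
#' @param pot_weights data.frame with columns plant_id, day, weight_g.
#' @param plants data.frame with columns plant_id, is_control, harvest_day.
#' @param final_weight,ttsw calibration constants (g).
#' @return data.frame plant_id, itw with attribute "ftsw" holding the
#'   per-plant trajectories (list of numeric vectors indexed by plant_id).
#' @export
derive_water_phenotypes <- function(pot_weights, plants, final_weight, ttsw) {
  stopifnot(all(c("plant_id", "day", "weight_g") %in% names(pot_weights)))
  ftsw_list <- list()
  itw <- numeric(nrow(plants))
  for (i in seq_len(nrow(plants))) {
    pid <- plants$plant_id[i]
    rows <- pot_weights[pot_weights$plant_id == pid, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    ftsw <- compute_ftsw_series(rows$weight_g, final_weight, ttsw,
                                is_control = plants$is_control[i],
                                day = rows$day)
    ftsw_list[[pid]] <- ftsw
    upto <- which(rows$day < plants$harvest_day[i])
    itw[i] <- if (length(upto)) compute_itw(ftsw[upto]) else 0
  }
  out <- data.frame(plant_id = plants$plant_id, itw = itw,
                    stringsAsFactors = FALSE)
  attr(out, "ftsw") <- ftsw_list
  out
}
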