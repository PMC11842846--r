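#' Simulate an asymmetric-division growth lineage
#'
#' Runs the two-step heterogeneity-generating process: at each division a
#' mother of area \eqn{A} splits into daughters \eqn{fA} and \eqn{(1-f)A}
#' with \eqn{f \sim N(0.5, \sigma_f)} truncated to (0.05, 0.95), so daughter
#' areas always sum exactly to the mother's area; between divisions each
#' cell grows for `growth_hours` hours, by default exponentially
#' (growth rate proportional to current size), sampled hourly. Nucleus area
#' tracks cell area through a fixed per-cell factor
#' \eqn{\rho e^{\varepsilon}}, \eqn{\varepsilon \sim N(0, \sigma_{nc})},
#' redrawn at each birth.
#'
#' Repeated multiplicative divisions make the log cell area a sum of i.i.d.
#' terms, so its variance grows linearly with generation and the terminal
#' population converges to a log-normal size distribution.
#'
#' @param params A [lineage_params()] object.
#' @return A tibble of class `lineage_table` with columns `cell_id`,
#'   `parent_id`, `generation`, `time_h`, `cell_area`, `nucleus_area`; one
#'   row per cell per hourly sample. `time_h` is absolute (generation g is
#'   born at `g * growth_hours`).
#' @seealso [lineage_to_population()], [lineage_params()]
#' @export
#' @examples
#' tab <- simulate_lineage(lineage_params(generations = 4, seed = 7))
#' head(tab)
simulate_lineage <- function(params) {
  if (!inherits(params, "lineage_params")) {
    abort("`params` must be created with `lineage_params()`.")
  }
  set.seed(params$seed)
  gh <- params$growth_hours
  hours <- seq(0, gh)
  n0 <- params$n_founders

  draw_fraction <- function(n) {
    if (params$division_asymmetry_sd == 0) return(rep(0.5, n))
    f <- rnorm(n, 0.5, params$division_asymmetry_sd)
    bad <- which(f <= 0.05 | f >= 0.95)
    while (length(bad) > 0) {
      f[bad] <- rnorm(length(bad), 0.5, params$division_asymmetry_sd)
      bad <- bad[f[bad] <= 0.05 | f[bad] >= 0.95]
    }
    f
  }
  draw_nc_factor <- function(n) {
    params$nc_ratio * exp(rnorm(n, 0, params$nc_noise_sd))
  }
  grow <- function(area0) {
    # area trajectory at hourly samples; rows = cells, cols = hours
    if (params$growth_law == "exponential") {
      outer(area0, exp(params$growth_rate * hours))
    } else {
      area0 + outer(area0 * params$growth_rate, hours)
    }
  }

  gen_rows <- vector("list", params$generations + 1L)
  # founder generation 0
  id <- seq_len(n0)
  state <- list(
    id = id, parent = rep(NA_integer_, n0), gen = rep(0L, n0),
    birth = rep(0, n0), area = rep(params$initial_area, n0),
    nc = draw_nc_factor(n0)
  )
  next_id <- n0 + 1L

  emit <- function(state) {
    traj <- grow(state$area)
    n <- length(state$id)
    tibble(
      cell_id = rep(state$id, each = length(hours)),
      parent_id = rep(state$parent, each = length(hours)),
      generation = rep(state$gen, each = length(hours)),
      time_h = rep(state$birth, each = length(hours)) + rep(hours, n),
      cell_area = as.vector(t(traj)),
      nucleus_area = rep(state$nc, each = length(hours)) * as.vector(t(traj))
    )
  }

  gen_rows[[1L]] <- emit(state)
  for (g in seq_len(params$generations)) {
    # areas at division = end of the growth window
    end_area <- if (params$growth_law == "exponential") {
      state$area * exp(params$growth_rate * gh)
    } else {
      state$area * (1 + params$growth_rate * gh)
    }
    n <- length(state$id)
    f <- draw_fraction(n)
    child_area <- c(f * end_area, (1 - f) * end_area)
    child_parent <- rep(state$id, 2L)
    child_id <- next_id + seq_len(2L * n) - 1L
    next_id <- next_id + 2L * n
    state <- list(
      id = child_id, parent = child_parent,
      gen = rep(g, 2L * n), birth = rep(state$birth + gh, 2L),
      area = child_area, nc = draw_nc_factor(2L * n)
    )
    gen_rows[[g + 1L]] <- emit(state)
  }
  out <- dplyr::bind_rows(gen_rows)
  out <- dplyr::arrange(out, .data$cell_id, .data$time_h)
  class(out) <- c("lineage_table", class(out))
  attr(out, "params") <- params
  out
}

#' Extract the live population at a time point
#'
#' Returns the paired cell and nucleus areas of every cell alive at
#' `time_h`. A mother sampled at the instant it divides is replaced by its
#' daughters (born at that same time), so no area is double-counted.
#'
#' @param table A `lineage_table` from [simulate_lineage()].
#' @param time_h Absolute time in hours; must match a sampled time.
#' @return A tibble with columns `cell_id`, `generation`, `cell_area`,
#'   `nucleus_area`.
#' @export
#' @examples
#' tab <- simulate_lineage(lineage_params(generations = 3, seed = 1))
#' pop <- lineage_to_population(tab, 18)
#' nrow(pop)  # 8 terminal cells
lineage_to_population <- function(table, time_h) {
  if (!inherits(table, "lineage_table") &&
      !all(c("cell_id", "parent_id", "time_h", "cell_area",
             "nucleus_area") %in% names(table))) {
    abort("`table` must be a lineage table.")
  }
  check_number(time_h, "time_h", lower = 0)
  rows <- dplyr::filter(table, abs(.data$time_h - .env$time_h) < 1e-9)
  if (nrow(rows) == 0) {
    abort(
      sprintf("no cells sampled at time %g h", time_h),
      class = "nucmorph_empty_selection"
    )
  }
  # drop mothers caught exactly at their division instant (their daughters,
  # born at that time, carry the area forward)
  kid <- !is.na(table$parent_id)
  if (any(kid)) {
    div_time <- tapply(table$time_h[kid], table$parent_id[kid], min)
    divided_now <- as.numeric(names(div_time))[abs(div_time - time_h) < 1e-9]
    rows <- dplyr::filter(rows, !(.data$cell_id %in% divided_now))
  }
  dplyr::select(rows, "cell_id", "generation", "cell_area", "nucleus_area")
}

#' Osmolarity of a water-diluted medium
#'
#' Computes the osmolarity of a mixture of pure water and culture medium:
#' water contributes no solute, so the osmolarity is the medium osmolarity
#' scaled by the medium volume fraction. A hypotonic-shock exchange into 95%
#' water / 5% medium takes ~290 mOsm to ~14.5 mOsm.
#'
#' @param medium_osmolarity Osmolarity of the undiluted medium (mOsm).
#' @param medium_fraction Volume fraction of medium in the mixture, in
#'   \[0, 1\].
#' @return Osmolarity of the mixture in mOsm.
#' @export
#' @examples
#' dilution_osmolarity(290, 0.05)  # 14.5
dilution_osmolarity <- function(medium_osmolarity, medium_fraction) {
  check_number(medium_osmolarity, "medium_osmolarity", lower = 0)
  check_number(medium_fraction, "medium_fraction", lower = 0, upper = 1)
  medium_osmolarity * medium_fraction
}

#' Write a lineage table to CSV
#'
#' @param table A `lineage_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_csv <- function(table, path) {
  cols <- c("cell_id", "parent_id", "generation", "time_h",
            "cell_area", "nucleus_area")
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}
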