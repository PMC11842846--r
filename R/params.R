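#' Parameters for the division-lineage simulator
#'
#' Bundles the knobs of the asymmetric-division / size-proportional-growth
#' process that seeds cell and nucleus area heterogeneity. Each division
#' splits a mother of area \eqn{A} into \eqn{fA} and \eqn{(1-f)A} with
#' \eqn{f} drawn from a Normal(0.5, `division_asymmetry_sd`) truncated to
#' (0.05, 0.95); between divisions the area grows for `growth_hours` hours.
#'
#' @param initial_area Founder cell area in square micrometres (> 0).
#' @param division_asymmetry_sd Standard deviation of the daughter area
#'   fraction around 0.5 (dimensionless, in \[0, 0.25\]). Zero gives exactly
#'   symmetric divisions. The default 0.05 makes ten division rounds
#'   accumulate \eqn{\mathrm{var}(\ln A) \approx 10 \cdot (2\sigma_f)^2
#'   \approx 0.1}, the steady-state log-variance of the default area model.
#' @param growth_rate Per-hour relative growth rate (1/h, >= 0).
#' @param growth_hours Hours of post-division growth tracked per generation.
#' @param nc_ratio Mean nucleus/cell area ratio (in (0, 1)).
#' @param nc_noise_sd Standard deviation of the multiplicative log-normal
#'   noise on the nucleus/cell ratio, redrawn once per cell at birth (>= 0).
#' @param generations Number of division rounds (integer >= 1).
#' @param n_founders Number of independent founder cells (integer >= 1).
#' @param growth_law `"exponential"` (rate proportional to current size, the
#'   default) or `"linear"` (rate fixed at the birth size) for sensitivity
#'   analyses.
#' @param seed RNG seed; identical parameters and seed give a bit-identical
#'   lineage table.
#'
#' @return A list of class `lineage_params`.
#' @seealso [simulate_lineage()]
#' @export
#' @examples
#' lineage_params(division_asymmetry_sd = 0.1, generations = 8)
lineage_params <- function(initial_area = 300,
                           division_asymmetry_sd = 0.05,
                           growth_rate = 0.035,
                           growth_hours = 6,
                           nc_ratio = 0.35,
                           nc_noise_sd = 0.2,
                           generations = 10,
                           n_founders = 1,
                           growth_law = c("exponential", "linear"),
                           seed = 1L) {
  check_number(initial_area, "initial_area", lower = 1e-12)
  check_number(division_asymmetry_sd, "division_asymmetry_sd", 0, 0.25)
  check_number(growth_rate, "growth_rate", lower = 0)
  check_number(growth_hours, "growth_hours", lower = 0)
  check_number(nc_ratio, "nc_ratio", lower = 1e-12, upper = 1 - 1e-12)
  check_number(nc_noise_sd, "nc_noise_sd", lower = 0)
  generations <- check_count(generations, "generations", 1L)
  n_founders <- check_count(n_founders, "n_founders", 1L)
  growth_law <- match.arg(growth_law)
  seed <- check_count(seed, "seed", lower = 0L)
  structure(
    list(
      initial_area = initial_area,
      division_asymmetry_sd = division_asymmetry_sd,
      growth_rate = growth_rate,
      growth_hours = growth_hours,
      nc_ratio = nc_ratio,
      nc_noise_sd = nc_noise_sd,
      generations = generations,
      n_founders = n_founders,
      growth_law = growth_law,
      seed = seed
    ),
    class = "lineage_params"
  )
}

#' @export
print.lineage_params <- function(x, ...) {
  cat("<lineage_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Parameters for the synthetic labeled monolayer generator
#'
#' Defaults encode the statistical structure reported for crowded epithelial
#' monolayers: mean-normalized areas log-normal with
#' \eqn{\ln x \sim N(\mu = -0.05, \sigma^2 = 0.095)} (so the exponent
#' denominator \eqn{2\sigma^2 = 0.19}), and rescaled aspect ratios
#' \eqn{x = (AR-1)/(\langle AR\rangle - 1)} following a unit-mean gamma with
#' shape `ar_gamma_k = 2.43`. Nucleus areas couple linearly to cell areas
#' through `nc_ratio` with multiplicative log-normal noise `nc_noise_sd`.
#'
#' Mark channels are rendered per nucleus with a DAPI-normalized level
#' `1 + slope * (nucleus_area - mean)/mean + noise` and a radial
#' periphery/center contrast `1 + coupling * (nucleus_area - mean)/mean`.
#' The default panel carries a repressive-mark channel (`"H3K27me3"`, slope
#' `mark_slope`, no radial coupling) and an active-mark channel (`"H3K9ac"`,
#' slope `-mark_slope`, coupling `radial_gradient_coupling`), mirroring the
#' opposite size couplings of facultative-heterochromatin and euchromatin
#' marks.
#'
#' @param n_cells Target number of cells (>= 4). The realized count is the
#'   nearest full lattice (`nx * ny` with `nx = ny = round(sqrt(n_cells))`).
#' @param field_size Image side length in pixels.
#' @param area_lognormal_mu,area_lognormal_sigma2 Parameters of
#'   \eqn{\ln(\mathrm{area}/\langle \mathrm{area}\rangle)}.
#' @param ar_gamma_k Shape of the unit-mean gamma for rescaled aspect ratios.
#' @param mean_ar Population mean aspect ratio (> 1).
#' @param nc_ratio,nc_noise_sd Nucleus/cell area coupling as in
#'   [lineage_params()].
#' @param mark_slope Signed slope of the normalized repressive-mark level per
#'   unit relative nucleus area (the active mark gets `-mark_slope`).
#' @param mark_noise_sd Standard deviation of the per-nucleus mark-level
#'   noise.
#' @param radial_gradient_coupling Signed dependence of the active mark's
#'   periphery/center intensity ratio on relative nucleus area.
#' @param channels Optional data frame with columns `name`, `slope`,
#'   `coupling` overriding the default two-mark panel.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param pixel_noise_sd Additive Gaussian pixel noise, as a fraction of the
#'   mean channel intensity (clipped at zero).
#' @param dapi_level Mean DAPI intensity level (arbitrary units).
#' @param lattice_jitter Seed-point jitter as a fraction of the lattice
#'   spacing.
#' @param capacity_iters,capacity_eta,coarse_factor Capacity-iteration
#'   controls for matching rendered cell areas to their log-normal targets.
#' @param metric_size_exponent Exponent of the per-seed metric size
#'   normalization; the default is calibrated so rendered cell area and
#'   elongation stay independent, matching the sampling model.
#' @param seed RNG seed; identical parameters and seed give a bit-identical
#'   monolayer.
#'
#' @return A list of class `monolayer_params`.
#' @seealso [generate_monolayer()]
#' @export
#' @examples
#' monolayer_params(n_cells = 100, field_size = 256)
monolayer_params <- function(n_cells = 1000,
                             field_size = 768,
                             area_lognormal_mu = -0.05,
                             area_lognormal_sigma2 = 0.19 / 2,
                             ar_gamma_k = 2.43,
                             mean_ar = 1.4,
                             nc_ratio = 0.35,
                             nc_noise_sd = 0.2,
                             mark_slope = -0.3,
                             mark_noise_sd = 0.1,
                             radial_gradient_coupling = 0.3,
                             channels = NULL,
                             pixel_size = 0.5,
                             pixel_noise_sd = 0.02,
                             dapi_level = 100,
                             lattice_jitter = 0.2,
                             capacity_iters = 10,
                             capacity_eta = 0.15,
                             coarse_factor = 3,
                             metric_size_exponent = 0.85,
                             seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", 4L)
  field_size <- check_count(field_size, "field_size", 16L)
  check_number(area_lognormal_mu, "area_lognormal_mu")
  check_number(area_lognormal_sigma2, "area_lognormal_sigma2", lower = 1e-12)
  check_number(ar_gamma_k, "ar_gamma_k", lower = 1e-6)
  check_number(mean_ar, "mean_ar", lower = 1 + 1e-9)
  check_number(nc_ratio, "nc_ratio", lower = 1e-12, upper = 1 - 1e-12)
  check_number(nc_noise_sd, "nc_noise_sd", lower = 0)
  check_number(mark_slope, "mark_slope")
  check_number(mark_noise_sd, "mark_noise_sd", lower = 0)
  check_number(radial_gradient_coupling, "radial_gradient_coupling")
  check_number(pixel_size, "pixel_size", lower = 1e-12)
  check_number(pixel_noise_sd, "pixel_noise_sd", lower = 0)
  check_number(dapi_level, "dapi_level", lower = 1e-12)
  check_number(lattice_jitter, "lattice_jitter", 0, 0.45)
  capacity_iters <- check_count(capacity_iters, "capacity_iters", 0L)
  check_number(capacity_eta, "capacity_eta", 0, 1)
  coarse_factor <- check_count(coarse_factor, "coarse_factor", 1L)
  check_number(metric_size_exponent, "metric_size_exponent", 0, 1)
  seed <- check_count(seed, "seed", lower = 0L)
  if (is.null(channels)) {
    channels <- tibble(
      name = c("H3K27me3", "H3K9ac"),
      slope = c(mark_slope, -mark_slope),
      coupling = c(0, radial_gradient_coupling)
    )
  } else {
    channels <- as_tibble(channels)
    stopifnot(all(c("name", "slope", "coupling") %in% names(channels)))
  }
  structure(
    list(
      n_cells = n_cells, field_size = field_size,
      area_lognormal_mu = area_lognormal_mu,
      area_lognormal_sigma2 = area_lognormal_sigma2,
      ar_gamma_k = ar_gamma_k, mean_ar = mean_ar,
      nc_ratio = nc_ratio, nc_noise_sd = nc_noise_sd,
      mark_slope = mark_slope, mark_noise_sd = mark_noise_sd,
      radial_gradient_coupling = radial_gradient_coupling,
      channels = channels,
      pixel_size = pixel_size, pixel_noise_sd = pixel_noise_sd,
      dapi_level = dapi_level, lattice_jitter = lattice_jitter,
      capacity_iters = capacity_iters, capacity_eta = capacity_eta,
      coarse_factor = coarse_factor,
      metric_size_exponent = metric_size_exponent,
      seed = seed
    ),
    class = "monolayer_params"
  )
}

#' @export
print.monolayer_params <- function(x, ...) {
  cat("<monolayer_params>\n")
  for (nm in setdiff(names(x), "channels")) {
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  channels: %s\n", paste(x$channels$name, collapse = ", ")))
  invisible(x)
}
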