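#' Literature compilation of lateral extension rates
#'
#' Returns the per-study linear (lateral) extension rates, in mm per year,
#' compiled for the four focal coral species. The species-level growth rates
#' used by the simulator are the arithmetic means of these entries.
#'
#' @return A data.frame with columns `species`, `extension_mm_yr`, `location`.
#' @seealso [mean_extension_rates()]
#' @export
extension_rate_studies <- function() {
  path <- system.file("extdata", "extension_rate_studies.csv",
                      package = "reefsim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Species-level mean lateral extension rates
#'
#' Arithmetic mean of the per-study lateral extension rates (mm/yr) for each
#' species, the values that parameterize radial colony growth.
#'
#' @param studies data.frame as returned by [extension_rate_studies()].
#' @return Named numeric vector of mean extension rates in mm/yr.
#' @export
mean_extension_rates <- function(studies = extension_rate_studies()) {
  out <- tapply(studies$extension_mm_yr, studies$species, mean)
  # fixed species order
  out[c("P_lobata", "P_lutea", "A_muricata", "P_damicornis")]
}

#' Eggs per cm2 from polyp density and polyp fecundity
#'
#' Area-specific fecundity computed as the product of polyp density
#' (polyps/cm2) and the number of eggs produced per polyp.
#'
#' @param polyps_per_cm2 polyp density, polyps per cm2 of colony surface.
#' @param eggs_per_polyp eggs produced per polyp.
#' @return Eggs per cm2 of colony surface.
#' @export
eggs_per_cm2_from_polyps <- function(polyps_per_cm2, eggs_per_polyp) {
  stopifnot(polyps_per_cm2 >= 0, eggs_per_polyp >= 0)
  polyps_per_cm2 * eggs_per_polyp
}

#' Default species parameter table
#'
#' The standard parameterization of the four focal Zanzibar reef corals:
#' two massive species (*Porites lobata*, *P. lutea*) and two branching
#' species (*Acropora muricata*, *Pocillopora damicornis*). Growth rates are
#' literature means (see [extension_rate_studies()]); reproduction constants,
#' thermal thresholds and size limits follow the standard parameter set.
#'
#' Columns (units):
#' \describe{
#'   \item{name}{species identifier}
#'   \item{morphology}{"massive" or "branching"}
#'   \item{extension_mm_yr}{mean lateral extension rate, mm/yr}
#'   \item{growth_cm_month}{radial growth per monthly time step, cm
#'     (= extension_mm_yr / 10 / 12)}
#'   \item{max_radius_cm}{maximum colony radius, cm}
#'   \item{spat_size_mm}{diameter of a newly settled spat, mm}
#'   \item{maturity_diam_cm}{mean colony diameter at reproductive maturity, cm}
#'   \item{eggs_per_cm2}{gametes or larvae per cm2 of colony surface}
#'   \item{polyps_per_cm2, eggs_per_polyp}{components of eggs_per_cm2 where
#'     published (NA otherwise)}
#'   \item{retention_factor}{recruits per larva; folds fertilization success,
#'     predation, retention and early mortality into one multiplier}
#'   \item{surface_factor}{ratio of true colony surface to the hemispherical
#'     surface of the average radius}
#'   \item{fixed_input_m2}{constant external recruit input per m2 of arena
#'     per recruitment event, supplied by adjacent reefs independently of the
#'     local stock (added after the retention multiplication: these are
#'     recruits, not larvae)}
#'   \item{events_per_year}{recruitment events per year (1 = annual spawner,
#'     12 = monthly brooder)}
#'   \item{mode}{reproductive mode}
#'   \item{min_bleach_T, all_bleach_T}{onset and saturation temperature of the
#'     bleaching response, degC of the 20-day statistic}
#'   \item{min_death_T, all_death_T}{onset and saturation temperature of
#'     post-bleaching mortality, degC}
#'   \item{connectivity}{multiple of the internal stock-recruitment supplied
#'     externally by neighbouring reefs}
#' }
#'
#' @return data.frame with one row per species, in fixed order
#'   P_lobata, P_lutea, A_muricata, P_damicornis.
#' @export
default_species_params <- function() {
  ext <- as.numeric(mean_extension_rates())
  data.frame(
    name          = c("P_lobata", "P_lutea", "A_muricata", "P_damicornis"),
    morphology    = c("massive", "massive", "branching", "branching"),
    extension_mm_yr = ext,
    growth_cm_month = ext / 10 / 12,
    max_radius_cm = c(300, 300, 50, 30),
    spat_size_mm  = c(1, 1, 1.2, 2),
    maturity_diam_cm = c(8, 8, 5.5, 5.5),
    eggs_per_cm2  = c(1210, 1375, 109.5, 2.5),
    polyps_per_cm2 = c(NA, 19.1, 15, NA),
    eggs_per_polyp = c(12, 72, 7.2, NA),
    retention_factor = c(1.0e-8, 1.0e-8, 4.5e-8, 1.5e-7),
    surface_factor = c(1.5, 1, 5, 3),
    fixed_input_m2 = c(0.01, 0.01, 0.01, 0.01),
    events_per_year = c(1, 1, 1, 12),
    mode = c("gonochoric spawner", "gonochoric spawner",
             "hermaphroditic spawner", "hermaphroditic brooder"),
    min_bleach_T = c(29.9, 29.9, 29.4, 30),
    all_bleach_T = c(31, 31, 31, 31),
    min_death_T  = c(29.4, 29.4, 28.2, 21.5),
    all_death_T  = c(32, 32, 32, 30.4),
    connectivity = c(1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Thermal thresholds for one species
#'
#' Convenience accessor returning the four temperature anchors of the
#' bleaching / mortality response as a list.
#'
#' @param species species name (row of [default_species_params()]).
#' @param params species parameter table.
#' @return list with `min_bleach_T`, `all_bleach_T`, `min_death_T`,
#'   `all_death_T` (degC).
#' @export
thermal_thresholds <- function(species, params = default_species_params()) {
  i <- match(species, params$name)
  if (is.na(i)) stop("unknown species: ", species)
  as.list(params[i, c("min_bleach_T", "all_bleach_T",
                      "min_death_T", "all_death_T")])
}
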