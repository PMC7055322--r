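#' Default taxonomic-group specification
#'
#' Fourteen taxonomic groups spanning aboveground and belowground biota, with
#' species-pool sizes, mean plot-level richness per land-use system (F forest,
#' J jungle rubber, R rubber monoculture, O oil palm monoculture), the
#' fraction of a converted plot's species drawn from the forest species pool
#' (turnover structure), and the number of plots lacking data for the group.
#' Richness is highest in forest and jungle rubber and lowest in monocultures
#' for most groups; soil prokaryotes run flat to increasing, mirroring the
#' few taxa whose total richness does not decline with conversion.
#'
#' @return A data frame with columns `group`, `pool`, `mean_F`, `mean_J`,
#'   `mean_R`, `mean_O`, `forest_overlap`, `n_missing`.
#' @export
default_taxa_spec <- function() {
  spec <- read.csv(text = "
group,pool,mean_F,mean_J,mean_R,mean_O,forest_overlap,n_missing
trees,180,80,45,8,4,0.50,0
understorey_plants,220,90,70,35,30,0.40,0
canopy_ants,160,70,55,30,22,0.45,0
parasitoid_wasps,400,120,100,60,45,0.40,0
birds,120,45,38,20,14,0.50,1
bats,40,12,10,5,4,0.60,0
butterflies,150,55,48,28,18,0.45,0
litter_invertebrates,260,85,70,40,30,0.40,0
testate_amoebae,90,35,32,25,22,0.55,1
oribatida,110,40,34,22,18,0.50,0
mesostigmata,70,25,21,13,10,0.50,0
fungi,500,150,140,110,100,0.45,2
bacteria,600,160,165,175,185,0.50,0
archaea,120,30,32,36,40,0.55,2
", strip.white = TRUE)
  spec
}

#' Default ecosystem-function indicator specification
#'
#' Thirty-six indicators grouped into ten ecosystem functions, each with a
#' direction flag (`higher_better` or `lower_better`), per-land-use mean, and
#' Gaussian noise standard deviation. Carbon stocks, decomposition and soil
#' respiration decline from forest to monocultures; greenhouse-gas and
#' nutrient-leaching fluxes (undesirable, `lower_better`) increase; soil
#' fertility improves toward oil palm (fertilized plots); transpiration is
#' U-shaped. Units are indicator-specific and only relative levels matter
#' for the threshold indices.
#'
#' @return A data frame with columns `indicator`, `fn_group`, `direction`,
#'   `mean_F`, `mean_J`, `mean_R`, `mean_O`, `sd`.
#' @export
default_function_spec <- function() {
  read.csv(text = "
indicator,fn_group,direction,mean_F,mean_J,mean_R,mean_O,sd
litterfall_npp,npp,higher_better,9,8,6,7,0.8
stem_increment,npp,higher_better,4,3.5,3,2.5,0.5
fine_root_production,npp,higher_better,3,2.6,2,1.8,0.4
harvest_npp,npp,higher_better,0,1.5,3.5,8,0.6
aboveground_carbon,plant_carbon,higher_better,150,90,40,35,12
coarse_root_carbon,plant_carbon,higher_better,35,22,10,9,3
fine_root_carbon,plant_carbon,higher_better,4,3.2,2.2,2,0.4
soc_topsoil,soil_carbon,higher_better,45,40,35,30,4
soc_subsoil,soil_carbon,higher_better,60,55,50,46,5
litter_carbon,soil_carbon,higher_better,8,6,3,2,0.7
n_mineralization,soil_fertility,higher_better,10,9,8,12,1.2
extractable_p,soil_fertility,higher_better,4,4.5,5,9,0.8
exch_ca,soil_fertility,higher_better,1.5,1.6,1.8,3.2,0.3
exch_k,soil_fertility,higher_better,0.25,0.25,0.3,0.5,0.05
exch_mg,soil_fertility,higher_better,0.5,0.5,0.6,1,0.1
base_saturation,soil_fertility,higher_better,20,22,25,45,4
soil_co2_efflux,soil_respiration,higher_better,15,14,12,10,1.2
n2o_flux,ghg_fluxes,lower_better,0.5,0.7,1,1.6,0.15
ch4_flux,ghg_fluxes,lower_better,-2,-1.5,-1,-0.3,0.3
co2_eq_flux,ghg_fluxes,lower_better,3,3.5,4.2,5,0.4
tdn_leaching,nutrient_leaching,lower_better,5,7,10,18,1.5
nitrate_leaching,nutrient_leaching,lower_better,3,4.5,7,14,1.2
ammonium_leaching,nutrient_leaching,lower_better,0.5,0.6,0.8,1.2,0.1
doc_leaching,nutrient_leaching,lower_better,8,9,10,12,1
ca_leaching,nutrient_leaching,lower_better,2,2.5,3,6,0.5
mg_leaching,nutrient_leaching,lower_better,1,1.2,1.5,3,0.25
al_leaching,nutrient_leaching,lower_better,0.8,1,1.4,2,0.2
p_leaching,nutrient_leaching,lower_better,0.1,0.12,0.15,0.3,0.03
litter_mass_loss,decomposition,higher_better,60,55,45,40,4
stand_transpiration,transpiration,higher_better,1.8,1.6,1.1,1.9,0.15
canopy_conductance,transpiration,higher_better,2.2,2,1.4,2.3,0.2
air_temperature,microclimate,lower_better,25,25.5,27,28,0.5
air_humidity,microclimate,higher_better,90,87,80,78,2
soil_temperature,microclimate,lower_better,24.5,25,26.5,27.5,0.4
soil_moisture,microclimate,higher_better,0.35,0.33,0.28,0.26,0.02
vapour_pressure_deficit,microclimate,lower_better,0.5,0.7,1.1,1.3,0.1
", strip.white = TRUE)
}

#' Default plot-level yield specification
#'
#' Mean and standard deviation of annual crop yield (kg per hectare per year)
#' per cropped land-use system: jungle rubber (J, dry rubber), rubber
#' monoculture (R, dry rubber) and oil palm (O, fresh fruit bunches).
#'
#' @return A data frame with columns `crop`, `mean`, `sd`.
#' @export
default_yield_spec <- function() {
  data.frame(
    crop = c("J", "R", "O"),
    mean = c(550, 900, 18000),
    sd   = c(140, 220, 3000)
  )
}

#' Default household survey specification
#'
#' Per-crop household counts (701 in total) and the linear yield-profit
#' relation `profit = a + b * yield + e` with heteroscedastic residual
#' standard deviation `sd(e) = gamma * yield` (USD per hectare per year).
#' Slopes put mean profits near 200 (J), 450 (R) and 1100 (O) USD
#' ha\eqn{^{-1}} yr\eqn{^{-1}}, spanning the 0-1000 USD range of the
#' profit-expectation grid.
#'
#' @return A data frame with columns `crop`, `n`, `intercept`, `slope`,
#'   `gamma`.
#' @export
default_household_spec <- function() {
  data.frame(
    crop      = c("J", "R", "O"),
    n         = c(171L, 280L, 250L),
    intercept = c(20, 30, 0),
    slope     = c(0.35, 0.45, 0.06),
    gamma     = c(0.12, 0.15, 0.015)
  )
}

#' Build a synthetic-data configuration
#'
#' Assembles and validates the configuration driving all four synthetic-data
#' generators. The defaults emulate a 4 land-use-system x 2 landscape x 4
#' replicate design (32 plots of 50 m x 50 m), 14 taxonomic groups, 36
#' ecosystem-function indicators in 10 functions, and a 701-household
#' yield-profit survey.
#'
#' @param n_landscapes Number of landscape blocks (default 2).
#' @param n_replicates Replicate plots per land-use system and landscape
#'   (default 4).
#' @param systems Ordered land-use labels; exactly four, default
#'   `c("F","J","R","O")` with `F` the zero-profit forest reference.
#' @param taxa Taxonomic-group specification, see [default_taxa_spec()].
#' @param functions Indicator specification, see [default_function_spec()].
#' @param yields Plot yield specification, see [default_yield_spec()].
#' @param households Household specification, see [default_household_spec()].
#' @param seed Integer root seed; every generator derives its own substream
#'   from it via [stream_seed()].
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 42)
#' nrow(cfg$functions)  # 36 indicators
synth_config <- function(n_landscapes = 2,
                         n_replicates = 4,
                         systems = c("F", "J", "R", "O"),
                         taxa = default_taxa_spec(),
                         functions = default_function_spec(),
                         yields = default_yield_spec(),
                         households = default_household_spec(),
                         seed = 1L) {
  if (n_landscapes < 1 || n_replicates < 1) {
    stop("configuration error: all counts must be >= 1", call. = FALSE)
  }
  if (length(systems) != 4 || anyDuplicated(systems) ||
      !"F" %in% systems) {
    stop("configuration error: exactly 4 distinct land-use labels ",
         "including the forest reference 'F' are required", call. = FALSE)
  }
  need <- c("group", "pool", paste0("mean_", c("F", "J", "R", "O")),
            "forest_overlap")
  if (!all(need %in% names(taxa))) {
    stop("configuration error: taxa spec misses columns: ",
         paste(setdiff(need, names(taxa)), collapse = ", "), call. = FALSE)
  }
  if (is.null(taxa$n_missing)) taxa$n_missing <- 0L
  if (any(taxa$forest_overlap < 0 | taxa$forest_overlap > 1)) {
    stop("configuration error: forest_overlap must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(taxa$pool < 1)) {
    stop("configuration error: species pools must be >= 1", call. = FALSE)
  }
  if (!all(functions$direction %in% c("higher_better", "lower_better"))) {
    stop("configuration error: unknown direction flag in function spec",
         call. = FALSE)
  }
  if (any(is.na(functions$fn_group)) || any(functions$fn_group == "")) {
    stop("configuration error: unknown function group in indicator metadata",
         call. = FALSE)
  }
  if (any(households$gamma < 0)) {
    stop("configuration error: heteroscedasticity coefficient gamma ",
         "must be >= 0", call. = FALSE)
  }
  if (any(households$n < 1)) {
    stop("configuration error: household counts must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_landscapes = as.integer(n_landscapes),
      n_replicates = as.integer(n_replicates),
      systems = systems,
      taxa = taxa,
      functions = functions,
      yields = yields,
      households = households,
      seed = as.integer(seed),
      idr_per_usd = 13389.413 # 2015 average exchange rate, metadata only
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  plots:      %d landscapes x 4 systems x %d replicates = %d\n",
              x$n_landscapes, x$n_replicates,
              x$n_landscapes * 4L * x$n_replicates))
  cat(sprintf("  taxa:       %d groups\n", nrow(x$taxa)))
  cat(sprintf("  functions:  %d indicators in %d groups\n",
              nrow(x$functions), length(unique(x$functions$fn_group))))
  cat(sprintf("  households: %d\n", sum(x$households$n)))
  cat(sprintf("  seed:       %d\n", x$seed))
  invisible(x)
}
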