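#' Default run configuration
#'
#' Nested list of every tunable the run-level commands consume, in the
#' units used throughout the package. Any subset can be overridden from a
#' YAML file ([read_run_config()]) or by argument; unknown keys are
#' rejected so typos fail loudly.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    constants = list(rho_w = 1025, nu = 1.0e-6, g = 9.81, kappa = 0.41,
                     seconds_per_year = 3.156e7,
                     sigma = 0.283, k = 0.113, n_exp = 2.26, M_c = 0.1,
                     rho_c = 2850, r_f = 5),
    chemistry = list(Omega = c(3, 10),
                     grain_classes = c("mud", "silt", "fine_sand", "sand",
                                       "coarse_sand"),
                     phi0 = 0.4, L = 0.05, sphere_factor = 1),
    transport = list(H = 1, q = "capacity", A1 = 0.3, rho_s = 2850,
                     St_low = 30, St_high = 75, duty_cycle = 1,
                     capacity_coef = 0.05, shields_method = "brownlie",
                     shields_const = 0.03),
    bioturbation = list(n_taxa_per_group = 50, phi = 0.4, rho_s = 2850,
                        level_model = "excavation"),
    grid = list(D_min = 1e-5, D_max = 5e-3, n_D = 60,
                u_star_min = 0.005, u_star_max = 0.5, n_u_star = 60,
                Omega = 3),
    scenario = list(Omega_t1 = 3, Omega_t2 = 3, biomass_factor = 1,
                    bodysize_factor = 1, couple_depth = FALSE)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose top-level sections mirror
#' [default_run_config()] and merges it over the defaults. Only keys that
#' exist in the defaults are accepted.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, path = "config")
}

merge_config <- function(base, user, path) {
  for (key in names(user)) {
    if (!key %in% names(base)) {
      stop("unknown configuration field: ", path, "$", key, call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], as.list(user[[key]]),
                                  paste0(path, "$", key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

config_fluid <- function(config) {
  cc <- config$constants
  fluid_constants(rho_w = cc$rho_w, nu = cc$nu, g = cc$g, kappa = cc$kappa,
                  seconds_per_year = cc$seconds_per_year)
}

config_kinetics <- function(config) {
  cc <- config$constants
  mineral_kinetics(sigma = cc$sigma, k = cc$k, n_exp = cc$n_exp,
                   M_c = cc$M_c, rho_c = cc$rho_c, r_f = cc$r_f)
}

# weak but dependency-free content hash for provenance sidecars
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

write_run_outputs <- function(df, out, config) {
  if (is.null(out)) return(invisible(NULL))
  utils::write.csv(df, out, row.names = FALSE)
  meta <- list(package = "seafloorenergy",
               version = as.character(utils::packageVersion("seafloorenergy")),
               seed = config$seed,
               config_hash = config_hash(config),
               config = unclass(config))
  jsonlite::write_json(meta, paste0(out, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out)
}

log_config <- function(config, what) {
  message(sprintf("[seafloorenergy] %s: seed=%s config=%s", what,
                  config$seed, config_hash(config)))
}

#' Cementation fluxes over saturation states and grain sizes
#'
#' One row per (Omega, grain class) pair of the configured chemistry
#' section; deterministic.
#'
#' @param config A `run_config` list.
#' @param out Optional CSV output path (a `.meta.json` provenance sidecar
#'   is written next to it).
#' @return A `data.frame` with columns `Omega`, `grain_class`, `D_m`,
#'   `E_chem_J_m2_yr`.
#' @export
#' @examples
#' run_chem()
run_chem <- function(config = default_run_config(), out = NULL) {
  ch <- config$chemistry
  if (length(ch$Omega) == 0L) {
    stop("chemistry$Omega must list at least one saturation state",
         call. = FALSE)
  }
  if (length(ch$grain_classes) == 0L) {
    stop("chemistry$grain_classes must list at least one grain size",
         call. = FALSE)
  }
  log_config(config, "chem-flux")
  kin <- config_kinetics(config)
  grid <- expand.grid(grain_class = ch$grain_classes, Omega = ch$Omega,
                      stringsAsFactors = FALSE)
  grid$D_m <- resolve_grain_size(grid$grain_class)
  grid$E_chem_J_m2_yr <- vapply(seq_len(nrow(grid)), function(i) {
    as.numeric(cementation_energy_flux(grid$Omega[i], grid$D_m[i],
                                       phi0 = ch$phi0, L = ch$L, kin = kin,
                                       sphere_factor = ch$sphere_factor))
  }, numeric(1))
  df <- grid[, c("Omega", "grain_class", "D_m", "E_chem_J_m2_yr")]
  write_run_outputs(df, out, config)
  df
}

#' Quiet-water flux comparison: bioturbation box plots vs chemical bands
#'
#' Builds (or reads) a reworking table, evaluates both bioturbation
#' end-member models per taxon, computes per-group and pooled flux
#' distributions, the chemical flux bands over the configured grain
#' classes and saturation states, and the order-of-magnitude spans of the
#' whole comparison.
#'
#' @param config A `run_config` list.
#' @param table_path Optional path to a reworking table (CSV/XLSX); when
#'   `NULL` a synthetic table is generated from `config$seed`.
#' @param out Optional CSV path for the distribution table (bands go to
#'   `<out>` with `band` rows; provenance sidecar alongside).
#' @return A list with `table`, `distributions` (both models),
#'   `chemical_bands`, `fluxes` (per-taxon, mode-respecting),
#'   `bio_span_decades`, and `span_decades` (all fluxes).
#' @export
run_figure2 <- function(config = default_run_config(), table_path = NULL,
                        out = NULL) {
  log_config(config, "figure2")
  fluid <- config_fluid(config)
  kin <- config_kinetics(config)
  bio <- config$bioturbation
  tbl <- if (is.null(table_path)) {
    synthesize_reworking_table(seed = config$seed,
                               n_taxa_per_group = bio$n_taxa_per_group)
  } else {
    read_reworking_table(table_path)
  }
  fx <- bioturbation_fluxes(tbl, model = "by_mode", phi = bio$phi,
                            rho_s = bio$rho_s, fluid = fluid)
  dists <- rbind(
    flux_distributions(tbl, "excavation", by_mode = TRUE, phi = bio$phi,
                       rho_s = bio$rho_s, fluid = fluid),
    flux_distributions(tbl, "crack_propagation", by_mode = TRUE,
                       phi = bio$phi, rho_s = bio$rho_s, fluid = fluid))
  bands <- run_chem(config)
  pos <- fx$flux[fx$flux > 0]
  bio_span <- log10(max(pos) / min(pos))
  all_flux <- c(pos, bands$E_chem_J_m2_yr)
  span <- log10(max(all_flux) / min(all_flux))
  if (!is.null(out)) write_run_outputs(dists, out, config)
  list(table = tbl, distributions = dists, chemical_bands = bands,
       fluxes = fx, bio_span_decades = bio_span, span_decades = span)
}

#' Ratio maps under stepped bioturbation scenarios
#'
#' Computes four physical-to-chemical ratio grids sharing the configured
#' axes, with the constant bioturbation term stepped through none, lower
#' quartile, median, and upper quartile of the excavation fluxes of the
#' reworking table. The cementation-favorable cell count is nonincreasing
#' across that sequence.
#'
#' @inheritParams run_figure2
#' @param out Optional path prefix; each grid is written to
#'   `<out>_<level>.csv` in long form with a provenance sidecar.
#' @return A list with `levels` (the four flux constants), `grids`
#'   (named list of `ratio_grid` objects), and `favorable_fraction`
#'   (named numeric).
#' @export
run_figure3 <- function(config = default_run_config(), table_path = NULL,
                        out = NULL) {
  log_config(config, "figure3")
  fluid <- config_fluid(config)
  kin <- config_kinetics(config)
  g <- config$grid
  tr <- config$transport
  bio <- config$bioturbation
  if (g$n_D < 1 || g$n_u_star < 1) stop("grid must be non-empty", call. = FALSE)
  D_axis <- 10^seq(log10(g$D_min), log10(g$D_max), length.out = g$n_D)
  u_axis <- 10^seq(log10(g$u_star_min), log10(g$u_star_max),
                   length.out = g$n_u_star)
  tbl <- if (is.null(table_path)) {
    synthesize_reworking_table(seed = config$seed,
                               n_taxa_per_group = bio$n_taxa_per_group)
  } else {
    read_reworking_table(table_path)
  }
  levels <- bioturbation_levels(tbl, model = bio$level_model, phi = bio$phi,
                                rho_s = bio$rho_s, fluid = fluid)
  grids <- lapply(names(levels), function(lv) {
    ratio_map(D_axis, u_axis, Omega = g$Omega, bio_flux = levels[[lv]],
              level = lv, phi0 = config$chemistry$phi0,
              L = config$chemistry$L, kin = kin,
              sphere_factor = config$chemistry$sphere_factor,
              H = tr$H, q = tr$q, rho_s = tr$rho_s, A1 = tr$A1,
              duty_cycle = tr$duty_cycle, capacity_coef = tr$capacity_coef,
              fluid = fluid, St_low = tr$St_low, St_high = tr$St_high,
              shields_method = tr$shields_method,
              shields_const = tr$shields_const)
  })
  names(grids) <- names(levels)
  fav <- vapply(grids, cementation_favorable_fraction, numeric(1))
  if (!is.null(out)) {
    for (lv in names(grids)) {
      rg <- grids[[lv]]
      long <- expand.grid(D_m = rg$D_axis, u_star_m_s = rg$u_star_axis)
      long$E_sed_J_m2_yr <- as.vector(rg$E_sed)
      long$ratio <- as.vector(rg$ratio)
      write_run_outputs(long, paste0(out, "_", lv, ".csv"), config)
    }
  }
  list(levels = levels, grids = grids, favorable_fraction = fav)
}

#' Run a substrate-stability scenario from configuration
#'
#' @param config A `run_config` list (section `scenario`).
#' @param out Optional JSON output path.
#' @return A `scenario_result` (see [scenario_deltaF()]).
#' @export
run_scenario <- function(config = default_run_config(), out = NULL) {
  log_config(config, "scenario")
  sc <- config$scenario
  res <- scenario_deltaF(Omega_t1 = sc$Omega_t1, Omega_t2 = sc$Omega_t2,
                         biomass_factor = sc$biomass_factor,
                         bodysize_factor = sc$bodysize_factor,
                         couple_depth = sc$couple_depth,
                         kin = config_kinetics(config))
  if (!is.null(out)) {
    payload <- list(package = "seafloorenergy",
                    version = as.character(
                      utils::packageVersion("seafloorenergy")),
                    seed = config$seed,
                    config_hash = config_hash(config),
                    F_t1 = res$F_t1, F_t2 = res$F_t2, delta_F = res$delta_F,
                    perturbations = res$perturbations)
    jsonlite::write_json(payload, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  res
}
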