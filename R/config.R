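#' Builtin scenario names
#'
#' `builtin:main` is the reference configuration (90% core sequestration,
#' piecewise-linear continental growth); `builtin:core85` / `core95` /
#' `core97` rescale the initial BSE seed for alternative core sequestration
#' fractions; `builtin:campbell_growth` switches the continental growth
#' curve to the exponentially relaxing alternative.
#'
#' @return Character vector of builtin names.
#' @export
builtin_config_names <- function() {
  paste0("builtin:", c("main", "core85", "core95", "core97", "campbell_growth"))
}

builtin_params <- function(name) {
  switch(name,
    main = p_params(),
    core85 = p_params(core_fraction = 0.85),
    core95 = p_params(core_fraction = 0.95),
    core97 = p_params(core_fraction = 0.97),
    campbell_growth = p_params(growth = list(
      model = "exponential", A0_frac = 0.01, t_knee = 1.5e9, frac_knee = 2 / 3
    )),
    stop("unknown builtin configuration '", name, "'; known: ",
      paste(builtin_config_names(), collapse = ", "),
      call. = FALSE
    )
  )
}

#' Assemble a full run configuration
#'
#' @param model A [p_params()] object.
#' @param structure A [p_structure()] object.
#' @param seeding A [seed_spec()] (its `bse_total` defaults to the value
#'   implied by `model$core_fraction`).
#' @param scenario Scenario name string.
#' @param stride Snapshot decimation stride for written trajectories.
#' @return An object of class `run_config`.
#' @export
run_config <- function(model = p_params(), structure = p_structure(),
                       seeding = seed_spec(
                         bse_total = bse_seed_for_core_fraction(model$core_fraction)
                       ),
                       scenario = "main", stride = 100) {
  validate_params(model, structure)
  structure(
    list(
      scenario = scenario, model = model, structure = structure,
      seeding = seeding, stride = stride
    ),
    class = "run_config"
  )
}

#' Load a run configuration
#'
#' Accepts either a path to a JSON configuration file or a builtin name
#' (`"builtin:main"`, `"builtin:core85"`, `"builtin:core95"`,
#' `"builtin:core97"`, `"builtin:campbell_growth"`). The result is fully
#' validated; schema violations raise a single error itemizing the
#' offending keys.
#'
#' @param x Path or builtin name.
#' @return A [run_config()].
#' @examples
#' cfg <- load_config("builtin:main")
#' cfg$model$epsilon # 0.30
#' @export
load_config <- function(x) {
  if (startsWith(x, "builtin:")) {
    name <- sub("^builtin:", "", x)
    path <- system.file("extdata", "configs", paste0(name, ".json"),
      package = "phoscycle"
    )
    if (!nzchar(path)) {
      # fall back to in-code defaults (e.g. during development)
      return(run_config(model = builtin_params(name), scenario = name))
    }
    return(parse_config(jsonlite::read_json(path), source = x))
  }
  if (!file.exists(x)) stop("configuration file not found: ", x, call. = FALSE)
  parse_config(jsonlite::read_json(x), source = x)
}

parse_config <- function(raw, source = "<config>") {
  need <- setdiff(c("scenario", "model", "structure", "seeding"), names(raw))
  if (length(need)) {
    stop("invalid configuration ", source, ": missing sections ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  m <- raw$model
  params <- p_params(
    et = lapply(m$et, as.numeric),
    alpha = m$alpha, beta = m$beta,
    aeolian_p_rate = m$aeolian_p_rate, aeolian_mode = m$aeolian_mode,
    atm_cap = m$atm_cap, ocean_sat_conc = m$ocean_sat_conc,
    rainout_land_frac = m$rainout_land_frac,
    riverine_ms_frac = m$riverine_ms_frac,
    epsilon = m$epsilon, tau_sub = m$tau_sub,
    mixing = lapply(m$mixing, as.numeric),
    volcanism = lapply(m$volcanism, as.numeric),
    hydrothermal = lapply(m$hydrothermal, as.numeric),
    seaspray_rate = m$seaspray_rate,
    growth = c(
      list(model = m$growth$model),
      lapply(m$growth[c("A0_frac", "t_knee", "frac_knee")], as.numeric)
    ),
    cc_rock_growth = isTRUE(m$cc_rock_growth),
    core_fraction = m$core_fraction,
    dt = m$dt, n_steps = m$n_steps, p_molar_mass = m$p_molar_mass
  )
  s <- raw$structure
  struct <- p_structure(
    rock_masses = unlist(s$rock_masses)[RESERVOIRS],
    modern_p = unlist(s$modern_p)[RESERVOIRS],
    ocean_volume = s$ocean_volume,
    area_earth = s$area_earth, area_ocean = s$area_ocean,
    area_land_modern = s$area_land_modern,
    rho_cc = s$rho_cc, rho_mantle = s$rho_mantle
  )
  if (any(is.na(struct$rock_masses)) || any(is.na(struct$modern_p))) {
    stop("invalid configuration ", source,
      ": structure must define rock_masses and modern_p for all reservoirs",
      call. = FALSE
    )
  }
  seeding <- seed_spec(
    bse_total = raw$seeding$bse_total,
    caps = lapply(raw$seeding$caps, as.numeric),
    rng_seed = raw$seeding$rng_seed %||% 1L
  )
  run_config(
    model = params, structure = struct, seeding = seeding,
    scenario = raw$scenario, stride = raw$stride %||% 100
  )
}

#' Write a run configuration as JSON
#'
#' The written file round-trips through [load_config()] to an identical
#' configuration.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  payload <- list(
    scenario = config$scenario,
    stride = config$stride,
    model = unclass(config$model),
    structure = list(
      rock_masses = as.list(config$structure$rock_masses),
      modern_p = as.list(config$structure$modern_p),
      ocean_volume = config$structure$ocean_volume,
      area_earth = config$structure$area_earth,
      area_ocean = config$structure$area_ocean,
      area_land_modern = config$structure$area_land_modern,
      rho_cc = config$structure$rho_cc,
      rho_mantle = config$structure$rho_mantle
    ),
    seeding = list(
      bse_total = config$seeding$bse_total,
      caps = config$seeding$caps,
      rng_seed = config$seeding$rng_seed
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Deterministic fingerprint of the full parameter and structure set,
#' recorded in every output file for reproducibility.
#'
#' @param params A [p_params()].
#' @param structure A [p_structure()].
#' @return Character scalar.
#' @export
config_hash <- function(params, structure) {
  txt <- jsonlite::toJSON(
    list(model = unclass(params), structure = unclass(structure)),
    auto_unbox = TRUE, digits = NA
  )
  # small polynomial rolling hash; avoids a digest dependency
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> scenario '%s': BSE seed %.3g kg, %d steps x %g yr\n",
    x$scenario, x$seeding$bse_total, as.integer(x$model$n_steps), x$model$dt
  ))
  invisible(x)
}
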