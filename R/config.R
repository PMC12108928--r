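# Material configuration files (YAML or JSON) and schema validation.
#
# Layout:
#   fatigue:
#     su: 10            # MPa, nominal ultimate tensile strength
#     sigma_f: 7        # MPa, single-cycle fatigue strength (pulsatile, R = 0)
#     beta: -0.09       # fatigue life exponent (negative)
#     e_modulus: 2      # MPa
#     hardening_exp: 0.3
#     strength_coeff: 15  # MPa
#     paris_c: 1e-7     # mm/cycle per (MPa*sqrt(mm))^m
#     paris_m: 3
#   hyperelastic:       # optional material-card helpers
#     mu0: 0.67         # MPa
#     nu: 0.45
#
# The Basquin parameters must be calibrated on pulsatile (stress ratio R = 0)
# tests: the Gerber correction maps every counted cycle onto that reference
# curve, so sigma_f / beta fitted at another stress ratio would bias every
# life estimate.

.material_keys <- c("su", "sigma_f", "beta", "e_modulus", "hardening_exp",
                    "strength_coeff", "paris_c", "paris_m")

#' Read a material configuration file
#'
#' Reads YAML (`.yml` / `.yaml`) or JSON (`.json`) with a `fatigue` section
#' holding the [material_properties()] fields, and an optional `hyperelastic`
#' section with `mu0` (MPa) and `nu` used by [neo_hookean_params()]. Missing
#' or invalid keys raise an error naming the key.
#'
#' @param path Path to the config file.
#' @return A list with `material` (a `leaflet_material`) and `hyperelastic`
#'   (a list with `mu0`, `nu`, `c10`, `d1`, or `NULL` when absent).
#' @export
read_material_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("material config '%s' not found", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop(sprintf("unsupported config extension '.%s' (use .yaml or .json)", ext),
         call. = FALSE)
  }
  if (is.null(cfg$fatigue)) {
    stop("material config must have a `fatigue` section", call. = FALSE)
  }
  missing <- setdiff(.material_keys, names(cfg$fatigue))
  if (length(missing) > 0L) {
    stop(sprintf("material config missing fatigue key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- .material_keys[!vapply(cfg$fatigue[.material_keys],
                                function(v) is.numeric(v) && length(v) == 1L,
                                logical(1))]
  if (length(bad) > 0L) {
    stop(sprintf("fatigue key(s) not single numbers: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  material <- do.call(material_properties, cfg$fatigue[.material_keys])
  hyper <- NULL
  if (!is.null(cfg$hyperelastic)) {
    h <- cfg$hyperelastic
    for (k in c("mu0", "nu")) {
      if (is.null(h[[k]])) {
        stop(sprintf("hyperelastic section missing key: %s", k), call. = FALSE)
      }
    }
    nh <- neo_hookean_params(h$mu0, h$nu)
    hyper <- list(mu0 = h$mu0, nu = h$nu, c10 = nh$c10, d1 = nh$d1)
  }
  list(material = material, hyperelastic = hyper)
}

#' Path to the packaged demo material configuration
#'
#' The packaged constants are synthetic placeholders of plausible magnitude
#' for glutaraldehyde-fixed bovine pericardium; the fitted values used for
#' the published life table come from external cyclic tests and are not
#' public. Use them for demonstrations and smoke tests, not for absolute
#' life predictions.
#'
#' @return Path to `demo_material.yaml` inside the installed package.
#' @export
demo_material_path <- function() {
  system.file("extdata", "demo_material.yaml", package = "valvefatigue",
              mustWork = TRUE)
}

#' Published reference fatigue lives of the three virtual patients
#'
#' Returns the packaged table of predicted leaflet fatigue lives (cycles) at
#' the top (inner-surface) and bottom (outer-surface) maximum-stress
#' integration points of virtual patients A, B and C. The governing life of
#' a patient is the minimum over the two surfaces; combine with
#' [cycles_to_duration()] to express it in calendar time at a given heart
#' rate.
#'
#' @return A data frame with columns `patient`, `integration_point`,
#'   `life_cycles`.
#' @export
#' @examples
#' ref <- reference_lives()
#' gov <- tapply(ref$life_cycles, ref$patient, min)
#' cycles_to_duration(gov[["B"]], bpm = 70)$years
reference_lives <- function() {
  path <- system.file("extdata", "reference_lives.csv",
                      package = "valvefatigue", mustWork = TRUE)
  utils::read.csv(path, fileEncoding = "UTF-8")
}
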