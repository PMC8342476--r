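# YAML configuration: a single document with sections
# constants / species / environments / temperature. Omitted entries fall back
# to package defaults (reference constants, the four archetype species, the
# evolutionary + growth environment presets, default temperature responses);
# the provenance of every piece (default vs user) is recorded.

.SPECIES_FIELDS <- c("label", "ptype", "beta", "k_ccat", "xi", "K_p", "g_s",
                     "allocation_bounds", "Ca_over_Ci", "tradeoff",
                     "n_rubisco", "n_fit")
.ENV_FIELDS <- c("label", "I", "T_leaf", "N_t", "C_m", "C_a", "Ca_over_Ci",
                 "Cm_over_Ci", "O")
.SPECIES_REQUIRED <- c("ptype", "beta", "k_ccat", "xi", "K_p", "g_s")
.ENV_REQUIRED <- c("I", "T_leaf", "N_t")

#' Load a model configuration
#'
#' Reads a YAML configuration with sections `constants`, `species`,
#' `environments` and `temperature`. Every section is optional: an empty
#' configuration yields the reference constants, the four photosynthetic-type
#' archetypes, the built-in environment presets and the default temperature
#' responses. User entries override or extend the defaults by name. Unknown
#' sections or fields are rejected; missing required species/environment
#' fields raise an error naming the field.
#'
#' @param path path to a YAML file, or `NULL` for an all-defaults
#'   configuration.
#' @return An object of class `photo_config`: list with `constants`,
#'   `species` (named list of [species_params()]), `environments` (named list
#'   of [environment_spec()]), `tparams`, and a `provenance` record.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
    yaml::read_yaml(path) %||% list()
  }
  known <- c("constants", "species", "environments", "temperature")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  constants <- do.call(stoichiometry_constants, as.list(raw$constants %||% list()))
  tp_raw <- raw$temperature %||% list()
  tp_raw <- lapply(tp_raw, function(e) {
    e$H <- .from_yaml_inf(e$H)
    e
  })
  tparams <- do.call(temperature_params, tp_raw)

  species <- species_archetypes()
  sp_prov <- stats::setNames(rep("default", length(species)), names(species))
  for (nm in names(raw$species %||% list())) {
    entry <- raw$species[[nm]]
    unknown <- setdiff(names(entry), .SPECIES_FIELDS)
    if (length(unknown)) {
      stop("species '", nm, "': unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    miss <- setdiff(.SPECIES_REQUIRED, names(entry))
    if (length(miss)) {
      stop("species '", nm, "' is missing required field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    entry$label <- entry$label %||% nm
    if (!is.null(entry$allocation_bounds)) {
      entry$allocation_bounds <- lapply(entry$allocation_bounds, as.numeric)
    }
    if (!is.null(entry$tradeoff)) {
      entry$tradeoff <- do.call(rubisco_tradeoff, entry$tradeoff)
    }
    species[[nm]] <- do.call(species_params, entry)
    sp_prov[nm] <- "user"
  }

  environments <- environment_presets()
  env_prov <- stats::setNames(rep("default", length(environments)),
                              names(environments))
  for (nm in names(raw$environments %||% list())) {
    entry <- raw$environments[[nm]]
    unknown <- setdiff(names(entry), .ENV_FIELDS)
    if (length(unknown)) {
      stop("environment '", nm, "': unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    miss <- setdiff(.ENV_REQUIRED, names(entry))
    if (length(miss)) {
      stop("environment '", nm, "' is missing required field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    entry$label <- entry$label %||% nm
    environments[[nm]] <- do.call(environment_spec, entry)
    env_prov[nm] <- "user"
  }

  tp_prov <- stats::setNames(rep("default", length(tparams)), names(tparams))
  tp_prov[names(tp_raw)] <- "user"
  structure(list(constants = constants, species = species,
                 environments = environments, tparams = tparams,
                 provenance = list(constants = attr(constants, "provenance"),
                                   species = sp_prov, environments = env_prov,
                                   temperature = tp_prov)),
            class = "photo_config")
}

.from_yaml_inf <- function(x) {
  if (is.null(x)) return(x)
  if (is.character(x) && tolower(x) %in% c("inf", ".inf")) return(Inf)
  as.numeric(x)
}

#' Save a configuration to YAML
#'
#' Writes the fully resolved configuration (all constants, species,
#' environments and temperature entries) so that loading the written file
#' reproduces the configuration field for field.
#'
#' @param config a `photo_config` from [load_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "photo_config"))
  sp <- lapply(config$species, function(s) {
    out <- s[c("label", "ptype", "beta", "k_ccat", "xi", "K_p", "g_s",
               "Ca_over_Ci")]
    out$allocation_bounds <- lapply(s$allocation_bounds, as.numeric)
    out$tradeoff <- unclass(s$tradeoff)
    if (!is.null(s$n_rubisco)) out$n_rubisco <- s$n_rubisco
    if (!is.null(s$n_fit)) out$n_fit <- s$n_fit
    out
  })
  ev <- lapply(config$environments, function(e) {
    out <- list(label = e$label, I = e$I, T_leaf = e$T_leaf, N_t = e$N_t,
                Cm_over_Ci = e$Cm_over_Ci, O = e$O)
    if (!is.null(e$C_m)) out$C_m <- e$C_m
    if (!is.null(e$C_a)) out$C_a <- e$C_a
    if (!is.null(e$Ca_over_Ci)) out$Ca_over_Ci <- e$Ca_over_Ci
    out
  })
  tp <- lapply(unclass(config$tparams), function(e) {
    e$H <- if (is.infinite(e$H)) ".inf" else e$H
    e
  })
  doc <- list(constants = unclass(config$constants)[],
              species = sp, environments = ev, temperature = tp)
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}
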