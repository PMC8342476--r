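#' Stoichiometric and biophysical constants of the allocation model
#'
#' Returns the constant set that converts nitrogen investments into biochemical
#' capacities and couples the electron-transport chains to ATP/NADPH supply.
#' Defaults are the published reference values for the model's stoichiometry
#' (Rubisco site density per nitrogen, cytochrome-f nitrogen cost and electron
#' capacity, photosystem/LHC chlorophyll and nitrogen costs, C4-enzyme kinetic
#' constants, leaf optics). Any value can be overridden; the provenance of each
#' field (`"default"` or `"user"`) is recorded in the `"provenance"` attribute
#' so that configuration files can be reported faithfully.
#'
#' Fields beyond the core stoichiometry table are model-level conventions that
#' the package exposes rather than hard-codes:
#' \describe{
#'   \item{protein_N_fraction}{nitrogen mass fraction of protein (0.16), used to
#'     convert enzyme molecular weight to nitrogen cost per catalytic site.}
#'   \item{h_per_atp}{protons required per ATP by the ATP synthase (default 4);
#'     together with the 2 H+ per electron of the Q-cycle this sets the ATP
#'     yield of cyclic electron transport.}
#'   \item{N_ps_fraction}{fraction of total leaf nitrogen available to the
#'     photosynthetic apparatus (default 0.75, linear map).}
#'   \item{R_d}{day respiration (umol m-2 s-1, default 0).}
#'   \item{Vpr}{PEP-regeneration cap on the C4 cycle (default `Inf`).}
#'   \item{o2_diff_ratio}{relative diffusivity/solubility of O2 vs CO2 across
#'     the bundle-sheath interface (0.047), used for the O2 elevation term.}
#' }
#'
#' @param ... named overrides of any constant.
#' @return An object of class `photo_constants` (named list).
#' @examples
#' cs <- stoichiometry_constants(Theta = 0.9)
#' cs$Theta
#' attr(cs, "provenance")[["Theta"]]
#' @export
stoichiometry_constants <- function(...) {
  defaults <- list(
    c_E       = 1.27e-3,  # umol Rubisco sites per umol N
    c_N       = 8.85,     # mol N per mmol cytochrome f
    cyt_Jmax  = 172,      # mmol e- per mmol cyt f per s
    e_ATP     = 4 / 3,    # electrons per ATP, linear chain
    f         = 0.15,     # spectral quality correction
    alpha     = 0.84,     # leaf absorptance
    Theta     = 0.7,      # light-response convexity
    Jmax_CL   = 3,        # CET Jmax scaling with cyt f
    n_Chl     = 0.0158887,# chlorophyll per unit thylakoid nitrogen
    PSI       = 2,        # mmol PSI per mol Chl
    PSII      = 2.5,      # mmol PSII per mol Chl
    pI_Chl    = 184,      # mol Chl per mol PSI
    pII_Chl   = 60,       # mol Chl per mol PSII
    l_Chl     = 13,       # mol Chl per mol LHC
    pI_N      = 32.8,     # mol N per mol Chl, PSI
    pII_N     = 83.3,     # mol N per mol Chl, PSII
    l_N       = 26,       # mol N per mol Chl, LHC
    MW_PEPC   = 96000,    # Da
    MW_PPDK   = 95000,    # Da
    kcat_PEPC = 66,       # s-1
    kcat_PPDK = 6.02,     # s-1
    protein_N_fraction = 0.16,
    h_per_atp = 4,
    N_ps_fraction = 0.75,
    R_d       = 0,
    Vpr       = Inf,
    o2_diff_ratio = 0.047
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out <- utils::modifyList(defaults, overrides)
  bad <- names(out)[!vapply(out, function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0,
                            logical(1))]
  bad <- setdiff(bad, c("R_d"))  # R_d may be zero
  if (!(is.numeric(out$R_d) && length(out$R_d) == 1 && out$R_d >= 0)) {
    stop("R_d must be a non-negative number", call. = FALSE)
  }
  if (length(bad)) {
    stop("constants must be strictly positive scalars: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prov <- stats::setNames(rep("default", length(out)), names(out))
  prov[names(overrides)] <- "user"
  structure(out, provenance = prov, class = "photo_constants")
}

#' @export
print.photo_constants <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<photo_constants> (", sum(prov == "user"), " user override(s) )\n", sep = "")
  df <- data.frame(value = unlist(x), provenance = prov[names(x)])
  print(df)
  invisible(x)
}

# Feasible range of the LET proportion p given the chlorophyll bookkeeping:
# LHC_LET >= 0 requires p * (1000 - PSI * pI_Chl) >= PSII * pII_Chl.
feasible_p_range <- function(constants = stoichiometry_constants()) {
  denom <- 1000 - constants$PSI * constants$pI_Chl
  if (denom <= 0) stop("PSI chlorophyll cost exceeds total chlorophyll budget", call. = FALSE)
  p_min <- constants$PSII * constants$pII_Chl / denom
  c(min(1, p_min), 1)
}

# gas constant, J mol-1 K-1
.R_GAS <- 8.314

.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop(name, " must be a single number", call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(name, " must be in [", lower, ", ", upper, "], got ", x, call. = FALSE)
  }
  invisible(x)
}
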