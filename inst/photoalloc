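#!/usr/bin/env Rscript
# photoalloc command-line interface
#
#   photoalloc simulate  --config FILE --species NAME --environment NAME --out FILE
#                        [--sweep Ci|T|N --values a,b,c]
#   photoalloc optimize  --config FILE --species NAME --environment NAME --out FILE
#                        [--restarts N --seed INT]
#   photoalloc delta-n   --config FILE --species NAME --environment NAME
#                        [--growth-environment NAME] --out FILE [--seed INT]
#   photoalloc scan-env  --config FILE --species NAME --data FILE --out FILE
#                        [--seed INT]
#   photoalloc fit-compare --config FILE --species NAME --environment NAME
#                        [--growth-environment NAME] --data FILE --out FILE
#
# CSV outputs for tabular results (curves, surfaces), JSON for single results.

suppressPackageStartupMessages({
  library(photoalloc)
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the photoalloc CLI requires the 'optparse' package")
  }
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || args[1] %in% c("-h", "--help")) {
  cat("usage: photoalloc simulate|optimize|delta-n|scan-env|fit-compare [options]\n")
  quit(status = if (length(args) < 1) 1 else 0)
}
cmd <- args[1]

opts <- list(
  make_option("--config", type = "character", default = NULL),
  make_option("--species", type = "character", default = "C4"),
  make_option("--environment", type = "character", default = "evolutionary"),
  make_option("--growth-environment", type = "character",
              default = "growth_nitrogen", dest = "growth_environment"),
  make_option("--data", type = "character", default = NULL),
  make_option("--out", type = "character", default = "photoalloc_out"),
  make_option("--sweep", type = "character", default = NULL),
  make_option("--values", type = "character", default = NULL),
  make_option("--restarts", type = "integer", default = 20L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--log-level", type = "character", default = "info",
              dest = "log_level")
)
opt <- parse_args(OptionParser(option_list = opts), args = args[-1])

cfg <- load_config(opt$config)
species <- cfg$species[[opt$species]]
if (is.null(species)) stop("unknown species: ", opt$species)
env <- cfg$environments[[opt$environment]]
if (is.null(env)) stop("unknown environment: ", opt$environment)
settings <- optimizer_settings(n_starts = opt$restarts, seed = opt$seed)

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", path)
}

if (cmd == "simulate") {
  opt_res <- optimize_allocation(species, env, settings, cfg$constants,
                                 cfg$tparams)
  if (!is.null(opt$sweep)) {
    values <- as.numeric(strsplit(opt$values, ",")[[1]])
    curve <- response_curves(species, env, opt_res$alloc, opt_res$partition,
                             sweep = opt$sweep, values = values,
                             constants = cfg$constants, tparams = cfg$tparams)
    utils::write.csv(curve, opt$out, row.names = FALSE)
    message("wrote ", opt$out)
  } else {
    res <- simulate_assimilation(species, env, opt_res$alloc,
                                 opt_res$partition, cfg$constants, cfg$tparams)
    write_json(as.list(tidy(res)), opt$out)
  }
} else if (cmd == "optimize") {
  res <- optimize_allocation(species, env, settings, cfg$constants,
                             cfg$tparams)
  out <- c(as.list(glance(res)),
           list(allocation = as.list(setNames(tidy(res)$estimate,
                                              tidy(res)$term))))
  write_json(out, opt$out)
} else if (cmd == "delta-n") {
  genv <- cfg$environments[[opt$growth_environment]]
  if (is.null(genv)) stop("unknown growth environment: ", opt$growth_environment)
  evo <- optimize_allocation(species, env, settings, cfg$constants, cfg$tparams)
  gro <- optimize_allocation(species, genv, settings, cfg$constants, cfg$tparams)
  dn <- delta_n(evo, gro)
  write_json(list(delta_n = dn$delta_n, per_pool = as.list(dn$per_pool)),
             opt$out)
} else if (cmd == "scan-env") {
  if (is.null(opt$data)) stop("scan-env requires --data FILE")
  measured <- measurement_table(utils::read.csv(opt$data))
  scan <- environment_scan(species, measured,
                           settings = optimizer_settings(n_starts = 6,
                                                         seed = opt$seed),
                           constants = cfg$constants, tparams = cfg$tparams)
  utils::write.csv(scan$surface, opt$out, row.names = FALSE)
  message("argmin: I=", scan$argmin$I, " T=", scan$argmin$T_leaf,
          " C_m=", scan$argmin$C_m)
  message("wrote ", opt$out)
} else if (cmd == "fit-compare") {
  if (is.null(opt$data)) stop("fit-compare requires --data FILE")
  measured <- measurement_table(utils::read.csv(opt$data))
  genv <- cfg$environments[[opt$growth_environment]]
  evo <- optimize_allocation(species, env, settings, cfg$constants, cfg$tparams)
  gro <- optimize_allocation(species, genv, settings, cfg$constants, cfg$tparams)
  pred_evo <- predict_pools(species, genv, evo$alloc, evo$partition,
                            cfg$constants, cfg$tparams)
  pred_gro <- predict_pools(species, genv, gro$alloc, gro$partition,
                            cfg$constants, cfg$tparams)
  keep <- intersect(pred_evo$quantity, unique(measured$quantity))
  r_evo <- normalized_squared_residuals(pred_evo[pred_evo$quantity %in% keep, ],
                                        measured[measured$quantity %in% keep, ])
  r_gro <- normalized_squared_residuals(pred_gro[pred_gro$quantity %in% keep, ],
                                        measured[measured$quantity %in% keep, ])
  cmp <- compare_scenarios(r_evo, r_gro)
  write_json(list(wilcoxon_p = cmp$wilcoxon_p,
                  median_error = as.list(cmp$medians),
                  n = as.list(cmp$n)), opt$out)
} else {
  stop("unknown command: ", cmd)
}
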