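# Optimal nitrogen and energy allocation.
#
# The equality constraints (nitrogen fractions and energy fractions each sum
# to one) are eliminated by reparameterization: the nitrogen simplex through
# bounded stick-breaking (sigmoid-transformed free coordinates), the energy
# simplex through a softmax over the pools that can actually consume energy
# for the given species (structurally inactive pools are pinned to exactly
# zero, so a C3 plant's C4-cycle pool is 0, not merely small). The resulting
# unconstrained problem is solved by multistart Nelder-Mead from a
# deterministic Halton sequence plus physiology-informed starts.

#' Optimizer settings
#'
#' @param n_starts number of multistart points (default 20).
#' @param maxit maximum objective evaluations per start (default 2000).
#' @param reltol relative objective tolerance (default 1e-8).
#' @param seed integer; offsets the deterministic Halton start sequence so
#'   that replicate pipelines are reproducible.
#' @param polish run a final refinement from the best start (default TRUE).
#' @return A list of settings.
#' @export
optimizer_settings <- function(n_starts = 20, maxit = 2000, reltol = 1e-8,
                               seed = 1L, polish = TRUE) {
  list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
       reltol = reltol, seed = as.integer(seed), polish = isTRUE(polish))
}

# Halton low-discrepancy sequence, n points in d dimensions
.halton <- function(n, d, start = 1) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  stopifnot(d <= length(primes))
  one <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  idx <- seq(start, length.out = n)
  sapply(seq_len(d), function(k) vapply(idx, one, numeric(1), b = primes[k]))
}

.sig <- function(z) 1 / (1 + exp(-pmin(pmax(z, -40), 40)))
.logit <- function(u) stats::qlogis(pmin(pmax(u, 1e-9), 1 - 1e-9))

# Problem description: active dimensions, bounds, shared model inputs.
.make_problem <- function(species, env, constants, tparams) {
  env <- resolve_cm(env, species)
  b <- species$allocation_bounds
  prange <- feasible_p_range(constants)
  plo <- max(b$p[1], prange[1])
  pup <- min(b$p[2], prange[2])
  if (plo > pup) stop("no feasible LET proportion under the given bounds", call. = FALSE)
  c4_free <- b$n_C4[2] > b$n_C4[1]
  pr_active <- env$O > 0
  pools <- c(f_cb_m = species$beta < 1,
             f_pr_m = species$beta < 1 && pr_active,
             f_cb_s = species$beta > 0,
             f_pr_s = species$beta > 0 && pr_active,
             f_c4  = b$n_C4[2] > 0)
  active <- names(pools)[pools]
  ubE_eff <- min(b$n_Etot[2], 1 - b$n_C4[1] - b$n_Jmax[1])
  n_free <- 1L + (if (c4_free) 1L else 0L) + 1L + (length(active) - 1L)
  list(species = species, env = env, constants = constants, tparams = tparams,
       bounds = b, plo = plo, pup = pup, c4_free = c4_free,
       active_pools = active, ubE_eff = ubE_eff, n_free = n_free)
}

# z -> (allocation, partition); NULL alloc with a penalty when infeasible
.decode <- function(z, prob) {
  b <- prob$bounds
  i <- 1L
  n_E <- b$n_Etot[1] + .sig(z[i]) * (prob$ubE_eff - b$n_Etot[1]); i <- i + 1L
  if (prob$c4_free) {
    ubC <- min(b$n_C4[2], 1 - n_E - b$n_Jmax[1])
    if (ubC < b$n_C4[1]) {
      return(list(penalty = -10 - 1000 * (b$n_C4[1] - ubC)))
    }
    n_C4 <- b$n_C4[1] + .sig(z[i]) * (ubC - b$n_C4[1]); i <- i + 1L
  } else {
    n_C4 <- b$n_C4[1]
  }
  n_J <- 1 - n_E - n_C4
  if (n_J < b$n_Jmax[1] - 1e-12 || n_J > b$n_Jmax[2] + 1e-12) {
    return(list(penalty = -10 - 1000 * max(b$n_Jmax[1] - n_J, n_J - b$n_Jmax[2])))
  }
  n_J <- min(max(n_J, 0), 1)
  p <- prob$plo + .sig(z[i]) * (prob$pup - prob$plo); i <- i + 1L
  k <- length(prob$active_pools)
  logits <- c(if (k > 1) z[i:(i + k - 2L)] else numeric(0), 0)
  w <- exp(pmin(pmax(logits, -40), 40))
  f <- stats::setNames(rep(0, 5), c("f_cb_m", "f_pr_m", "f_cb_s", "f_pr_s", "f_c4"))
  f[prob$active_pools] <- w / sum(w)
  list(alloc = allocation(n_E, n_C4, n_J, p),
       partition = energy_partition(f[["f_cb_m"]], f[["f_pr_m"]], f[["f_cb_s"]],
                                    f[["f_pr_s"]], f[["f_c4"]]))
}

# encode a (n_E, n_C4, p, fractions) guess into z (inverse of .decode)
.encode <- function(prob, n_E, n_C4, p, fractions) {
  b <- prob$bounds
  z <- .logit((n_E - b$n_Etot[1]) / max(prob$ubE_eff - b$n_Etot[1], 1e-12))
  if (prob$c4_free) {
    ubC <- min(b$n_C4[2], 1 - n_E - b$n_Jmax[1])
    z <- c(z, .logit((n_C4 - b$n_C4[1]) / max(ubC - b$n_C4[1], 1e-12)))
  }
  z <- c(z, .logit((p - prob$plo) / max(prob$pup - prob$plo, 1e-12)))
  k <- length(prob$active_pools)
  if (k > 1) {
    fr <- pmax(fractions[prob$active_pools], 1e-6)
    fr <- fr / sum(fr)
    z <- c(z, log(fr[-k]) - log(fr[k]))
  }
  unname(z)
}

.objective <- function(z, prob) {
  dec <- .decode(z, prob)
  if (!is.null(dec$penalty)) return(dec$penalty)
  res <- tryCatch(
    simulate_assimilation(prob$species, prob$env, dec$alloc, dec$partition,
                          prob$constants, prob$tparams),
    error = function(e) NULL)
  if (is.null(res)) return(-1e6)
  res$A
}

# physiology-informed start points (in z-space)
.heuristic_starts <- function(prob) {
  b <- prob$bounds
  clip <- function(x, lo, up) min(max(x, lo), up)
  starts <- list()
  flat <- stats::setNames(rep(0, 5), c("f_cb_m", "f_pr_m", "f_cb_s", "f_pr_s", "f_c4"))
  flat[prob$active_pools] <- 1 / length(prob$active_pools)
  mk <- function(n_E, n_C4, p, fr) {
    n_E <- clip(n_E, b$n_Etot[1], prob$ubE_eff)
    n_C4 <- clip(n_C4, b$n_C4[1], min(b$n_C4[2], 1 - n_E - b$n_Jmax[1]))
    .encode(prob, n_E, n_C4, clip(p, prob$plo, prob$pup), fr)
  }
  # C3-style: most nitrogen in Rubisco, LET-dominated, energy mostly to the
  # mesophyll Calvin-Benson cycle
  fr1 <- flat
  if ("f_cb_m" %in% prob$active_pools) {
    fr1[] <- 0
    fr1[prob$active_pools] <- 0.05
    fr1["f_cb_m"] <- 0
    fr1["f_cb_m"] <- max(0, 1 - sum(fr1))
  }
  starts[[length(starts) + 1]] <- mk(0.55, 0, 0.95, fr1)
  # C4-style: nitrogen shared with the C4 cycle, more CET, energy split
  # between the pump and the bundle-sheath Calvin-Benson cycle
  if ("f_c4" %in% prob$active_pools) {
    fr2 <- flat
    fr2[] <- 0
    fr2[prob$active_pools] <- 0.04
    fr2["f_c4"] <- 0.3
    if ("f_cb_s" %in% prob$active_pools) fr2["f_cb_s"] <- 0.45
    fr2["f_cb_m"] <- if ("f_cb_m" %in% prob$active_pools) max(0, 1 - sum(fr2) + fr2["f_cb_m"]) else 0
    fr2 <- fr2 / sum(fr2)
    starts[[length(starts) + 1]] <- mk(0.35, 0.08, 0.6, fr2)
  }
  starts[[length(starts) + 1]] <- mk(0.45, 0.02, 0.8, flat)
  # bound-seeking start: optima of restricted types often pin the C4 pool at
  # its upper bound, which sigmoid coordinates approach only asymptotically
  if (b$n_C4[2] > b$n_C4[1]) {
    starts[[length(starts) + 1]] <- mk(0.45, b$n_C4[2] - 1e-9, 0.9, flat)
  }
  starts
}

# Active-set refinement: coordinates that land at (or asymptotically near) a
# bound converge slowly in sigmoid space, so re-polish with them pinned to
# the bound. Returns an improved (par-in-reduced-problem, value, prob) or NULL.
.active_set_refine <- function(z, value, prob, maxit, reltol) {
  dec <- .decode(z, prob)
  if (!is.null(dec$penalty)) return(NULL)
  best <- list(value = value, alloc = dec$alloc, partition = dec$partition)
  improved <- FALSE
  b <- prob$bounds
  span_c4 <- b$n_C4[2] - b$n_C4[1]
  pins <- list()
  if (prob$c4_free) {
    if (b$n_C4[2] - dec$alloc$n_C4 < 1e-3 * span_c4) {
      pins[[length(pins) + 1]] <- list(pool = "n_C4", at = b$n_C4[2])
    } else if (dec$alloc$n_C4 - b$n_C4[1] < 1e-3 * span_c4) {
      pins[[length(pins) + 1]] <- list(pool = "n_C4", at = b$n_C4[1])
    }
  }
  for (pin in pins) {
    sp2 <- prob$species
    sp2$allocation_bounds[[pin$pool]] <- c(pin$at, pin$at)
    prob2 <- .make_problem(sp2, prob$env, prob$constants, prob$tparams)
    z2 <- .encode(prob2, dec$alloc$n_Etot, pin$at, dec$alloc$p,
                  unlist(unclass(dec$partition)))
    v2 <- .objective(z2, prob2)
    pol <- .polish(z2, v2, prob2, maxit, reltol)
    if (pol$value > best$value) {
      d2 <- .decode(pol$par, prob2)
      best <- list(value = pol$value, alloc = d2$alloc,
                   partition = d2$partition)
      improved <- TRUE
    }
  }
  if (improved) best else NULL
}

# Energy-only refinement at frozen nitrogen fractions and p: the full-space
# simplex search tends to stall before fine-tuning the partition, while the
# reduced (smooth) energy sub-problem converges tightly.
.energy_refine <- function(alloc, partition, value, prob, maxit = 800) {
  k <- length(prob$active_pools)
  if (k <= 1) return(NULL)
  nm <- c("f_cb_m", "f_pr_m", "f_cb_s", "f_pr_s", "f_c4")
  mk <- function(w) {
    f <- stats::setNames(rep(0, 5), nm)
    f[prob$active_pools] <- w / sum(w)
    energy_partition(f[["f_cb_m"]], f[["f_pr_m"]], f[["f_cb_s"]],
                     f[["f_pr_s"]], f[["f_c4"]])
  }
  obj <- function(zen) {
    w <- exp(pmin(pmax(c(zen, 0), -40), 40))
    res <- tryCatch(
      simulate_assimilation(prob$species, prob$env, alloc, mk(w),
                            prob$constants, prob$tparams),
      error = function(e) NULL)
    if (is.null(res)) return(-1e6)
    res$A
  }
  fr <- pmax(unlist(unclass(partition))[prob$active_pools], 1e-6)
  z0 <- log(fr[-k]) - log(fr[k])
  fit <- stats::optim(unname(z0), obj,
                      method = if (k == 2) "BFGS" else "Nelder-Mead",
                      control = list(fnscale = -1, maxit = maxit,
                                     reltol = 1e-10))
  if (fit$value <= value) return(NULL)
  w <- exp(pmin(pmax(c(fit$par, 0), -40), 40))
  list(value = fit$value, alloc = alloc, partition = mk(w))
}

# repeated Nelder-Mead restarts from the incumbent until no further gain;
# each restart re-inflates the simplex, which matters on kinked ridges
.polish <- function(z, value, prob, maxit, reltol, rounds = 4) {
  for (r in seq_len(rounds)) {
    fit <- stats::optim(z, .objective, prob = prob, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = maxit,
                                       reltol = reltol))
    if (fit$value <= value * (1 + 1e-10) && fit$value <= value + 1e-12) {
      if (fit$value > value) {
        z <- fit$par; value <- fit$value
      }
      break
    }
    gain <- fit$value - value
    z <- fit$par
    value <- fit$value
    if (gain < abs(value) * reltol) break
  }
  list(par = z, value = value)
}

#' Optimize the nitrogen allocation and energy partition
#'
#' Finds the allocation `(n_Etot, n_C4, n_Jmax, p)` and five-pool energy
#' partition maximizing net CO2 assimilation for a species in an environment,
#' subject to the species' allocation bounds (C3 types cannot invest in the
#' C4 cycle), the sum-to-one constraints, and feasibility of the thylakoid
#' composition. Multistart local optimization with deterministic seeding;
#' the best local optimum is returned and re-verified by a fresh forward
#' simulation.
#'
#' @param species a [species_params()].
#' @param env an [environment_spec()].
#' @param settings see [optimizer_settings()].
#' @param constants see [stoichiometry_constants()].
#' @param tparams see [temperature_params()].
#' @return An object of class `photo_optim` with fields `alloc`, `partition`,
#'   `A_star`, `converged`, `n_restarts_used`, `best_start`,
#'   `constraint_violation`.
#' @export
optimize_allocation <- function(species, env, settings = optimizer_settings(),
                                constants = stoichiometry_constants(),
                                tparams = temperature_params()) {
  prob <- .make_problem(species, env, constants, tparams)
  if (prob$env$N_t == 0) {
    # degenerate: no nitrogen, A = 0 for any feasible allocation
    dec <- .decode(rep(0, prob$n_free), prob)
    return(structure(list(alloc = dec$alloc, partition = dec$partition,
                          A_star = 0, converged = TRUE, n_restarts_used = 0L,
                          best_start = 0L, constraint_violation = 0,
                          species = species$label, env = prob$env$label),
                     class = "photo_optim"))
  }
  starts <- .heuristic_starts(prob)
  n_extra <- max(0L, settings$n_starts - length(starts))
  if (n_extra > 0) {
    h <- .halton(n_extra, prob$n_free, start = settings$seed)
    h <- matrix(h, nrow = n_extra)
    for (r in seq_len(n_extra)) {
      starts[[length(starts) + 1]] <- .logit(h[r, ])
    }
  }
  starts <- starts[seq_len(min(length(starts), max(settings$n_starts, 1)))]
  best <- NULL
  best_val <- -Inf
  best_i <- 0L
  converged <- FALSE
  vals <- numeric(length(starts))
  for (s in seq_along(starts)) {
    fit <- stats::optim(starts[[s]], .objective, prob = prob,
                        method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = settings$maxit,
                                       reltol = settings$reltol))
    vals[s] <- fit$value
    if (fit$value > best_val) {
      best_val <- fit$value
      best <- fit$par
      best_i <- s
      converged <- fit$convergence == 0
    }
  }
  # full refinement (restart rounds, active-set, energy-only) is reserved for
  # full-budget settings; survey budgets (small maxit, e.g. grid scans)
  # prioritize throughput and consistency over the last ~0.1% of A
  do_refine <- settings$polish && settings$maxit >= 600
  if (settings$polish) {
    pol <- .polish(best, best_val, prob, settings$maxit, settings$reltol / 10,
                   rounds = if (do_refine) 4 else 2)
    if (pol$value >= best_val) {
      best_val <- pol$value
      best <- pol$par
      converged <- TRUE
    }
  }
  dec <- .decode(best, prob)
  if (do_refine) {
    ref <- .active_set_refine(best, best_val, prob, settings$maxit,
                              settings$reltol / 10)
    if (!is.null(ref)) {
      dec <- list(alloc = ref$alloc, partition = ref$partition)
      best_val <- ref$value
    }
    ref2 <- .energy_refine(dec$alloc, dec$partition, best_val, prob,
                           maxit = min(settings$maxit, 800))
    if (!is.null(ref2)) {
      dec <- list(alloc = ref2$alloc, partition = ref2$partition)
      best_val <- ref2$value
    }
  }
  res <- simulate_assimilation(species, prob$env, dec$alloc, dec$partition,
                               constants, tparams)
  viol <- max(abs(dec$alloc$n_Etot + dec$alloc$n_C4 + dec$alloc$n_Jmax - 1),
              abs(sum(unlist(unclass(dec$partition))) - 1))
  structure(list(alloc = dec$alloc, partition = dec$partition,
                 A_star = res$A, converged = converged,
                 n_restarts_used = length(starts), best_start = best_i,
                 constraint_violation = viol, start_values = vals,
                 species = species$label, env = prob$env$label,
                 result = res),
            class = "photo_optim")
}

#' @export
print.photo_optim <- function(x, ...) {
  cat("<photo_optim> ", x$species, " @ ", x$env, "\n", sep = "")
  cat("  A* = ", signif(x$A_star, 6), " umol m-2 s-1",
      if (!is.null(x$A_star_grid)) paste0(" (grid: ", signif(x$A_star_grid, 6), ")"),
      "\n", sep = "")
  print(x$alloc)
  print(x$partition)
  invisible(x)
}

# Evaluate one (alloc, p) grid point against several candidate energy
# partitions, sharing the capacity/light/enzyme computations.
.eval_point <- function(prob, alloc, candidates, best_so_far = -Inf) {
  species <- prob$species; env <- prob$env
  constants <- prob$constants
  caps <- capacities(alloc, env, species, constants)
  capsT <- apply_temperature(caps, species, env, prob$tparams)
  ab <- absorbed_irradiance(env$I, alloc$p, constants)
  J_LET <- electron_transport(ab$I_LET, capsT$Jmax_LET, constants$Theta)
  J_CET <- electron_transport(ab$I_CET, capsT$Jmax_CET, constants$Theta)
  supply <- energy_supply(J_LET, J_CET, constants)
  fluxes <- list(atp_rate = supply$atp_rate, nadph_rate = supply$nadph_rate)
  ej <- enzyme_limited(capsT, species, env, alloc$p, constants)
  # A <= min(A_c, atp/3, nadph/2): skip candidates that cannot beat the best
  ub <- min(ej$A_c, supply$atp_rate / 3, supply$nadph_rate / 2)
  if (ub <= best_so_far) {
    return(list(A = ub, skipped = TRUE, ej = ej, fluxes = fluxes, capsT = capsT))
  }
  best_A <- -Inf; best_part <- NULL
  for (part in candidates) {
    lj <- light_limited(capsT, fluxes, part, species, env,
                        p_psII = alloc$p, constants = constants)
    A <- min(lj$A_j, ej$A_c)
    if (A > best_A) {
      best_A <- A
      best_part <- part
    }
  }
  list(A = best_A, partition = best_part, skipped = FALSE, ej = ej,
       fluxes = fluxes, capsT = capsT)
}

# candidate partitions informed by the enzyme-limited flux pattern
.demand_candidates <- function(prob, ej, flat_only = FALSE) {
  nm <- c("f_cb_m", "f_pr_m", "f_cb_s", "f_pr_s", "f_c4")
  active <- prob$active_pools
  mkpart <- function(w) {
    w <- pmax(w, 0)
    w[setdiff(nm, active)] <- 0
    if (sum(w) <= 0) w[active] <- 1
    w <- w / sum(w)
    energy_partition(w[["f_cb_m"]], w[["f_pr_m"]], w[["f_cb_s"]], w[["f_pr_s"]],
                     w[["f_c4"]])
  }
  flat <- stats::setNames(rep(0, 5), nm)
  flat[active] <- 1
  out <- list(mkpart(flat))
  if (flat_only) return(out)
  atp_dem <- stats::setNames(c(3 * ej$V_c_m, 3.5 * ej$V_o_m, 3 * ej$V_c_s,
                               3.5 * ej$V_o_s, 2 * ej$V_p), nm)
  nad_dem <- stats::setNames(c(2 * ej$V_c_m, 2 * ej$V_o_m, 2 * ej$V_c_s,
                               2 * ej$V_o_s, 0), nm)
  if (sum(atp_dem) > 0) out[[length(out) + 1]] <- mkpart(atp_dem)
  if (sum(nad_dem) > 0) out[[length(out) + 1]] <- mkpart(nad_dem)
  if (sum(atp_dem) > 0 && sum(nad_dem) > 0) {
    out[[length(out) + 1]] <- mkpart(atp_dem / sum(atp_dem) + nad_dem / sum(nad_dem))
  }
  out
}

#' Exhaustive grid-search oracle for the allocation optimum
#'
#' Reference optimizer used to validate [optimize_allocation()]: an exhaustive
#' simplex-grid search over the nitrogen fractions and the LET proportion,
#' with a nested coarse search over energy partitions at every grid point
#' (flux-demand-proportional candidates, then a Nelder-Mead refinement of the
#' energy fractions at the most promising points). The returned `A_star_grid`
#' is guaranteed within grid spacing of the global optimum of the evaluated
#' surface; with `polish = TRUE` (default) a final local refinement over all
#' variables is run from the best grid point so the oracle value is comparable
#' to a continuous optimum.
#'
#' @inheritParams optimize_allocation
#' @param resolution grid points per axis (>= 5).
#' @param top_k number of best grid points whose energy partition is refined.
#' @param polish refine the best grid point over all variables (default TRUE).
#' @return A `photo_optim` object with additional field `A_star_grid`.
#' @export
grid_oracle <- function(species, env, resolution = 21,
                        constants = stoichiometry_constants(),
                        tparams = temperature_params(),
                        top_k = 25, polish = TRUE) {
  stopifnot(resolution >= 5)
  prob <- .make_problem(species, env, constants, tparams)
  b <- prob$bounds
  nE_vals <- seq(b$n_Etot[1], prob$ubE_eff, length.out = resolution)
  nC_vals <- if (prob$c4_free) {
    seq(b$n_C4[1], b$n_C4[2], length.out = resolution)
  } else b$n_C4[1]
  p_vals <- seq(prob$plo, prob$pup, length.out = resolution)
  pts <- list()
  for (nE in nE_vals) for (nC in nC_vals) {
    nJ <- 1 - nE - nC
    if (nJ >= b$n_Jmax[1] - 1e-12 && nJ <= b$n_Jmax[2] + 1e-12 && nJ >= 0) {
      pts[[length(pts) + 1]] <- c(nE, nC, max(nJ, 0))
    }
  }
  best_A <- -Inf
  evals <- vector("list", length(pts) * length(p_vals))
  k <- 0L
  for (pt in pts) for (p in p_vals) {
    k <- k + 1L
    alloc <- allocation(pt[1], pt[2], pt[3], p)
    ev0 <- .eval_point(prob, alloc, list(), best_so_far = Inf)  # enzyme only
    cands <- .demand_candidates(prob, ev0$ej)
    ev <- .eval_point(prob, alloc, cands, best_so_far = best_A)
    evals[[k]] <- list(alloc = alloc, A = ev$A, partition = ev$partition,
                       skipped = ev$skipped)
    if (!ev$skipped && ev$A > best_A) best_A <- ev$A
  }
  ord <- order(vapply(evals, `[[`, numeric(1), "A"), decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  best_grid <- NULL
  best_grid_A <- -Inf
  refined <- list()
  for (i in keep) {
    e <- evals[[i]]
    # refine the energy partition (and re-evaluate skipped points properly)
    zfull <- .encode(prob, e$alloc$n_Etot, e$alloc$n_C4, e$alloc$p,
                     unlist(unclass(e$partition %||%
                                      .demand_candidates(prob, NULL, flat_only = TRUE)[[1]])))
    n_nitro <- 1L + (if (prob$c4_free) 1L else 0L) + 1L
    k_en <- prob$n_free - n_nitro
    obj_en <- function(zen) .objective(c(zfull[seq_len(n_nitro)], zen), prob)
    if (k_en > 0) {
      fit <- stats::optim(zfull[-seq_len(n_nitro)], obj_en,
                          method = if (k_en == 1) "BFGS" else "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 400,
                                         reltol = 1e-10))
      val <- fit$value
      zcand <- c(zfull[seq_len(n_nitro)], fit$par)
    } else {
      val <- .objective(zfull, prob)
      zcand <- zfull
    }
    refined[[length(refined) + 1]] <- list(z = zcand, val = val)
    if (val > best_grid_A) {
      best_grid_A <- val
      best_grid <- zcand
    }
  }
  A_star_grid <- best_grid_A
  z_best <- best_grid
  if (polish) {
    # refine the leading candidates over all variables; the raw grid value
    # is kept in A_star_grid for dominance checks
    rord <- order(vapply(refined, `[[`, numeric(1), "val"), decreasing = TRUE)
    best_val <- best_grid_A
    for (i in rord[seq_len(min(3, length(rord)))]) {
      pol <- .polish(refined[[i]]$z, refined[[i]]$val, prob, maxit = 3000,
                     reltol = 1e-10)
      if (pol$value > best_val) {
        best_val <- pol$value
        z_best <- pol$par
      }
    }
  }
  dec <- .decode(z_best, prob)
  if (polish) {
    ref <- .active_set_refine(z_best, .objective(z_best, prob), prob,
                              maxit = 3000, reltol = 1e-10)
    if (!is.null(ref)) dec <- list(alloc = ref$alloc, partition = ref$partition)
  }
  res <- simulate_assimilation(species, prob$env, dec$alloc, dec$partition,
                               constants, tparams)
  structure(list(alloc = dec$alloc, partition = dec$partition,
                 A_star = res$A, A_star_grid = A_star_grid,
                 converged = TRUE, n_restarts_used = length(evals),
                 best_start = NA_integer_, constraint_violation = 0,
                 species = species$label, env = prob$env$label, result = res),
            class = "photo_optim")
}

#' Re-optimize the energy allocation with frozen nitrogen pools
#'
#' Implements the alternative plasticity model in which protein-level nitrogen
#' pools cannot change on the timescale of a measurement, but the energy
#' allocation — the five-pool partition and the proportion of linear electron
#' transport `p` — re-adjusts to the measurement environment. The nitrogen
#' fractions of `alloc` are kept fixed; `p` and the energy fractions are
#' optimized for `env`.
#'
#' @param alloc an [allocation()] (typically the growth-environment optimum).
#' @param species a [species_params()].
#' @param env the measurement environment.
#' @param settings see [optimizer_settings()].
#' @inheritParams optimize_allocation
#' @return A `photo_optim` object (the allocation keeps its nitrogen
#'   fractions; `p` and the partition are re-optimized).
#' @export
optimize_energy_given_nitrogen <- function(alloc, species, env,
                                           settings = optimizer_settings(n_starts = 8),
                                           constants = stoichiometry_constants(),
                                           tparams = temperature_params()) {
  prob <- .make_problem(species, env, constants, tparams)
  obj <- function(zpe) {
    p <- prob$plo + .sig(zpe[1]) * (prob$pup - prob$plo)
    k <- length(prob$active_pools)
    logits <- c(if (k > 1) zpe[2:k] else numeric(0), 0)
    w <- exp(pmin(pmax(logits, -40), 40))
    f <- stats::setNames(rep(0, 5), c("f_cb_m", "f_pr_m", "f_cb_s", "f_pr_s", "f_c4"))
    f[prob$active_pools] <- w / sum(w)
    a <- tryCatch(allocation(alloc$n_Etot, alloc$n_C4, alloc$n_Jmax, p),
                  error = function(e) NULL)
    if (is.null(a)) return(-1e6)
    part <- energy_partition(f[["f_cb_m"]], f[["f_pr_m"]], f[["f_cb_s"]],
                             f[["f_pr_s"]], f[["f_c4"]])
    res <- tryCatch(simulate_assimilation(species, prob$env, a, part,
                                          constants, tparams),
                    error = function(e) NULL)
    if (is.null(res)) return(-1e6)
    res$A
  }
  d <- length(prob$active_pools)  # 1 (for p) + d - 1 logits
  starts <- list(rep(0, d))
  starts[[2]] <- c(.logit((min(max(alloc$p, prob$plo), prob$pup) - prob$plo) /
                            max(prob$pup - prob$plo, 1e-12)), rep(0, d - 1))
  n_extra <- max(0L, settings$n_starts - length(starts))
  if (n_extra > 0) {
    h <- matrix(.halton(n_extra, d, start = settings$seed), nrow = n_extra)
    for (r in seq_len(n_extra)) starts[[length(starts) + 1]] <- .logit(h[r, ])
  }
  best <- NULL; best_val <- -Inf; best_i <- 0L; converged <- FALSE
  for (s in seq_along(starts)) {
    fit <- stats::optim(starts[[s]], obj,
                        method = if (d == 1) "BFGS" else "Nelder-Mead",
                        control = list(fnscale = -1, maxit = settings$maxit,
                                       reltol = settings$reltol))
    if (fit$value > best_val) {
      best_val <- fit$value; best <- fit$par; best_i <- s
      converged <- fit$convergence == 0
    }
  }
  p <- prob$plo + .sig(best[1]) * (prob$pup - prob$plo)
  k <- length(prob$active_pools)
  logits <- c(if (k > 1) best[2:k] else numeric(0), 0)
  w <- exp(pmin(pmax(logits, -40), 40))
  f <- stats::setNames(rep(0, 5), c("f_cb_m", "f_pr_m", "f_cb_s", "f_pr_s", "f_c4"))
  f[prob$active_pools] <- w / sum(w)
  new_alloc <- allocation(alloc$n_Etot, alloc$n_C4, alloc$n_Jmax, p,
                          scenario = alloc$scenario)
  part <- energy_partition(f[["f_cb_m"]], f[["f_pr_m"]], f[["f_cb_s"]],
                           f[["f_pr_s"]], f[["f_c4"]])
  res <- simulate_assimilation(species, prob$env, new_alloc, part, constants,
                               tparams)
  structure(list(alloc = new_alloc, partition = part, A_star = res$A,
                 converged = converged, n_restarts_used = length(starts),
                 best_start = best_i, constraint_violation = 0,
                 species = species$label, env = prob$env$label, result = res),
            class = "photo_optim")
}
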