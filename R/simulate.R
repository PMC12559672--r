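# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Synthetic metacommunity scenario configuration
#'
#' Defines a synthetic world of river-connected patches, whose water /
#' mudflat / vegetation composition tracks the hydrological regime, beside
#' stable surrounding lakes whose composition does not. River patches are
#' large and little disturbed (they sit in a protected floodplain); stable
#' lakes are smaller and carry more human disturbance. Patch areas are
#' drawn log-uniformly at construction from the config seed, so a config is
#' a fully reproducible world.
#'
#' @param n_river_patches number of regime-responsive river patches (12).
#' @param n_stable_patches number of stable surrounding lakes (10).
#' @param area_range_river,area_range_stable wetland-area ranges (km^2) for
#'   the log-uniform draw.
#' @param habitat_response named list regime -> c(water, mudflat,
#'   vegetation) fractions for river patches.
#' @param stable_fracs habitat fractions for stable patches (regime-free).
#' @param disturbance_range_river,disturbance_range_stable uniform ranges
#'   for the per-patch disturbance index.
#' @param gamma_disturbance exponential penalty rate on suitability per
#'   unit disturbance.
#' @param overdispersion optional gamma-Poisson shape (NULL = pure Poisson).
#' @param seed integer seed fixing the drawn world.
#' @return Object of class `scenario_config`; `$patches` holds the patch
#'   attribute table (patch_id, subregion, wetland_area, disturbance).
#' @export
scenario_config <- function(n_river_patches = 12L,
                            n_stable_patches = 10L,
                            area_range_river = c(5, 60),
                            area_range_stable = c(1.5, 4),
                            habitat_response = list(
                              ER = c(water = 0.30, mudflat = 0.30, vegetation = 0.40),
                              LR = c(water = 0.65, mudflat = 0.15, vegetation = 0.20),
                              NR = c(water = 0.45, mudflat = 0.25, vegetation = 0.30),
                              ED = c(water = 0.05, mudflat = 0.35, vegetation = 0.60)
                            ),
                            stable_fracs = c(water = 0.60, mudflat = 0.05,
                                             vegetation = 0.05),
                            disturbance_range_river = c(0, 0.5),
                            disturbance_range_stable = c(0.5, 1.5),
                            gamma_disturbance = 0.5,
                            overdispersion = NULL,
                            seed = 1L) {
  for (fr in habitat_response) {
    if (sum(fr) > 1 + 1e-9) stop("habitat fractions must sum to <= 1", call. = FALSE)
  }
  if (sum(stable_fracs) > 1 + 1e-9) stop("stable fractions must sum to <= 1", call. = FALSE)
  patches <- with_seed(derive_seed(seed, 1L), {
    log_unif <- function(n, range) exp(stats::runif(n, log(range[1L]), log(range[2L])))
    data.frame(
      patch_id = c(sprintf("R%02d", seq_len(n_river_patches)),
                   sprintf("S%02d", seq_len(n_stable_patches))),
      subregion = rep(c("DTL", "SLS"), c(n_river_patches, n_stable_patches)),
      patch_class = rep(c("river", "stable"), c(n_river_patches, n_stable_patches)),
      wetland_area = c(log_unif(n_river_patches, area_range_river),
                       log_unif(n_stable_patches, area_range_stable)),
      disturbance = c(stats::runif(n_river_patches, disturbance_range_river[1L],
                                   disturbance_range_river[2L]),
                      stats::runif(n_stable_patches, disturbance_range_stable[1L],
                                   disturbance_range_stable[2L])),
      stringsAsFactors = FALSE
    )
  })
  structure(list(
    n_river_patches = n_river_patches,
    n_stable_patches = n_stable_patches,
    habitat_response = habitat_response,
    stable_fracs = stable_fracs,
    gamma_disturbance = gamma_disturbance,
    overdispersion = overdispersion,
    seed = seed,
    patches = patches
  ), class = "scenario_config")
}

#' Synthetic species pool with functional-group habitat affinities
#'
#' Forty waterbird species by default, split over the nine functional
#' groups (dabbling ducks, diving ducks, diving fishers, gulls, large and
#' small wading birds, herbivorous geese, tuber-feeding birds, vegetation
#' gleaners). Each species gets the group's base affinity over (water,
#' mudflat, vegetation) with mild lognormal jitter, renormalized to sum to
#' 1, and a regional population drawn lognormally around a group-level
#' scale: the gregarious meadow and mudflat foragers (geese, waders,
#' tuber-feeders, gleaners) winter in large flocks, while open-water
#' divers, fishers and gulls occur at far lower numbers.
#'
#' @param n_species pool size (default 40; every group stays non-empty).
#' @param population_scale named vector of group-level expected population
#'   sizes (individuals).
#' @param population_sdlog lognormal spread of species populations around
#'   their group scale (default 0.5).
#' @param seed integer seed.
#' @return data frame: species, functional_group, aff_water, aff_mudflat,
#'   aff_vegetation, population.
#' @export
species_pool <- function(n_species = 40L,
                         population_scale = c(
                           dabbling_ducks = 8000, diving_ducks = 150,
                           diving_fishers = 120, gulls = 2000,
                           large_wading_birds = 6000,
                           small_wading_birds = 8000,
                           herbivorous_geese = 30000,
                           tuber_feeding_birds = 6000,
                           vegetation_gleaners = 8000),
                         population_sdlog = 0.4,
                         seed = 1L) {
  base <- list(
    dabbling_ducks      = c(0.70, 0.25, 0.05),
    diving_ducks        = c(0.95, 0.03, 0.02),
    diving_fishers      = c(0.90, 0.07, 0.03),
    gulls               = c(0.55, 0.40, 0.05),
    large_wading_birds  = c(0.30, 0.65, 0.05),
    small_wading_birds  = c(0.20, 0.75, 0.05),
    herbivorous_geese   = c(0.02, 0.08, 0.90),
    tuber_feeding_birds = c(0.30, 0.50, 0.20),
    vegetation_gleaners = c(0.10, 0.20, 0.70)
  )
  ngroups <- length(base)
  if (n_species < ngroups) {
    stop("need at least ", ngroups, " species, one per functional group",
         call. = FALSE)
  }
  # default composition mirrors a duck-dominated wintering assemblage
  weights <- c(6, 7, 7, 4, 3, 4, 3, 3, 3)
  sizes <- pmax(1L, floor(weights / sum(weights) * n_species))
  while (sum(sizes) < n_species) {
    i <- which.max(weights / sum(weights) * n_species - sizes)
    sizes[i] <- sizes[i] + 1L
  }
  while (sum(sizes) > n_species) {
    i <- which(sizes > 1L)[which.max(sizes[sizes > 1L])]
    sizes[i] <- sizes[i] - 1L
  }
  groups <- rep(names(base), sizes)
  with_seed(derive_seed(seed, 2L), {
    aff <- t(vapply(groups, function(g) {
      a <- base[[g]] * exp(stats::rnorm(3L, 0, 0.15))
      a / sum(a)
    }, numeric(3L)))
    pop <- population_scale[groups] *
      stats::rlnorm(n_species, 0, population_sdlog)
    data.frame(
      species = sprintf("sp%02d", seq_len(n_species)),
      functional_group = groups,
      aff_water = aff[, 1L], aff_mudflat = aff[, 2L],
      aff_vegetation = aff[, 3L],
      population = pop,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
}

#' Per-patch habitat areas under a hydrological regime
#'
#' River patches multiply their wetland area by the regime's habitat
#' fractions; stable patches use the fixed stable fractions regardless of
#' regime.
#'
#' @param config a [scenario_config()].
#' @param regime one of "ER", "LR", "NR", "ED".
#' @return data frame: patch_id, subregion, patch_class, wetland_area,
#'   water_area, mudflat_area, vegetation_area, disturbance.
#' @export
apply_regime <- function(config, regime) {
  stopifnot(inherits(config, "scenario_config"))
  if (!regime %in% names(config$habitat_response)) {
    stop("unknown regime: ", regime, call. = FALSE)
  }
  p <- config$patches
  river <- p$patch_class == "river"
  fr <- config$habitat_response[[regime]]
  sf <- config$stable_fracs
  p$water_area      <- p$wetland_area * ifelse(river, fr[[1L]], sf[[1L]])
  p$mudflat_area    <- p$wetland_area * ifelse(river, fr[[2L]], sf[[2L]])
  p$vegetation_area <- p$wetland_area * ifelse(river, fr[[3L]], sf[[3L]])
  p
}

#' Expected species-by-patch counts from habitat suitability
#'
#' Suitability of patch p for species i is the affinity-weighted habitat
#' area times an exponential disturbance penalty:
#' u_ip = (sum_h affinity_ih * area_ph) * exp(-gamma * disturbance_p).
#' The species' regional population B_i is allocated proportionally:
#' lambda_ip = B_i * u_ip / sum_p u_ip (all-zero suitability gives zeros),
#' so expected totals are conserved whenever any patch is suitable.
#'
#' @param areas per-patch habitat areas from [apply_regime()].
#' @param pool a [species_pool()].
#' @param config a [scenario_config()] (for the disturbance penalty).
#' @return matrix of expectations (rows = species, cols = patches).
#' @export
expected_counts <- function(areas, pool, config) {
  A <- as.matrix(areas[, c("water_area", "mudflat_area", "vegetation_area")])
  aff <- as.matrix(pool[, c("aff_water", "aff_mudflat", "aff_vegetation")])
  u <- aff %*% t(A)                                   # species x patch
  pen <- exp(-config$gamma_disturbance * areas$disturbance)
  u <- sweep(u, 2L, pen, `*`)
  tot <- rowSums(u)
  lambda <- matrix(0, nrow(u), ncol(u))
  ok <- tot > 0
  lambda[ok, ] <- pool$population[ok] * u[ok, , drop = FALSE] / tot[ok]
  dimnames(lambda) <- list(pool$species, areas$patch_id)
  lambda
}

#' Draw one period's survey counts
#'
#' Independent Poisson noise around the expectations (or gamma-Poisson when
#' the config sets an overdispersion shape). Zero counts are dropped from
#' the records: a survey row exists where birds were seen.
#'
#' @param lambda expectation matrix from [expected_counts()].
#' @param seed integer seed; identical seeds give identical draws.
#' @param period period label for the records.
#' @param patches patch attribute table (for subregions); defaults to
#'   patch ids with subregion "NA".
#' @param pool species pool (for functional groups).
#' @param overdispersion optional gamma shape; NULL = Poisson.
#' @return A [survey_set()] with one period.
#' @export
sample_counts <- function(lambda, seed, period = "T1", patches = NULL,
                          pool = NULL, overdispersion = NULL) {
  counts <- with_seed(seed, {
    lam <- as.vector(lambda)
    if (!is.null(overdispersion)) {
      lam <- lam * stats::rgamma(length(lam), shape = overdispersion,
                                 rate = overdispersion)
    }
    stats::rpois(length(lam), lam)
  })
  cm <- matrix(counts, nrow(lambda), ncol(lambda), dimnames = dimnames(lambda))
  idx <- which(cm > 0, arr.ind = TRUE)
  sub_of <- function(pid) {
    if (is.null(patches)) rep("NA", length(pid))
    else patches$subregion[match(pid, patches$patch_id)]
  }
  grp_of <- function(sp) {
    if (is.null(pool)) rep("NA", length(sp))
    else pool$functional_group[match(sp, pool$species)]
  }
  rec <- data.frame(
    period = rep(period, nrow(idx)),
    patch_id = colnames(cm)[idx[, 2L]],
    subregion = sub_of(colnames(cm)[idx[, 2L]]),
    species = rownames(cm)[idx[, 1L]],
    functional_group = grp_of(rownames(cm)[idx[, 1L]]),
    count = cm[idx],
    stringsAsFactors = FALSE
  )
  survey_set(rec, periods = period)
}

#' Simulate a four-regime survey suite
#'
#' Generates one survey period per hydrological regime in chronological
#' order ER, LR, NR, ED (early recession, late recession, normal recession,
#' extreme drought) via [apply_regime()] -> [expected_counts()] ->
#' [sample_counts()], with per-period seeds derived from the master seed.
#'
#' @param config a [scenario_config()].
#' @param pool a [species_pool()].
#' @param seed master integer seed.
#' @param regimes period order (default the four canonical regimes).
#' @return A [survey_set()] spanning the four periods.
#' @export
scenario_suite <- function(config, pool, seed = config$seed,
                           regimes = c("ER", "LR", "NR", "ED")) {
  stopifnot(inherits(config, "scenario_config"))
  sets <- lapply(seq_along(regimes), function(i) {
    areas <- apply_regime(config, regimes[i])
    lambda <- expected_counts(areas, pool, config)
    sample_counts(lambda, seed = derive_seed(seed, 100L + i),
                  period = regimes[i], patches = config$patches, pool = pool,
                  overdispersion = config$overdispersion)
  })
  survey_set(do.call(rbind, lapply(sets, function(s) s$records)),
             periods = regimes)
}
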