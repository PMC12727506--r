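## Synthetic-data generators.
##
## A Scenario fixes everything: the landscape (grid size, class mixture,
## per-class intensity distributions, ecoregion bands with biomes and
## mosaics), the score process (truth table, expert count, expert noise sd)
## and the species process (group structure, threat-category effects). Every
## generator is a pure function of the scenario: the same seed gives
## bitwise-identical output. Class composition is assigned by exact quota
## (largest remainder), and intensities by midpoint quantiles of the
## configured distribution, so the deterministic landscape has a closed-form
## expected BII; a sampling mode exists for stochastic tests.

## Evaluate an expression with a temporary RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max, kind = "Mersenne-Twister")
  expr
}

#' Exact-quota integer allocation
#'
#' Splits `n` units over weights by largest remainder (ties broken by
#' position), so counts are deterministic and sum to `n`.
#'
#' @param n Total count.
#' @param weights Non-negative weights summing to 1 (tolerance 1e-9).
#' @return Integer vector of counts, same names as `weights`.
#' @export
quota_counts <- function(n, weights) {
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  exact <- n * weights
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Default functional-group subset used by the bundled scenario
#'
#' A compact cross-section of the registry: two groups per vertebrate class
#' and each broad plant group, keeping bundled runs fast while exercising
#' vertebrate and plant score paths (including biomes and mosaics).
#'
#' @param registry Group registry from [load_group_registry()].
#' @return Character vector of group ids.
#' @export
scenario_default_groups <- function(registry = load_group_registry()) {
  pick <- function(cls, k) utils::head(
    registry$group_id[registry$taxon_class == cls & !registry$species_level], k)
  c(unlist(lapply(.vertebrate_classes, pick, k = 2)),
    unlist(lapply(.plant_classes, pick, k = 1)))
}

#' Construct a synthetic-data scenario
#'
#' Bundles every knob of the synthetic generators. The defaults emulate the
#' study conditions at desk scale: an 80/14/6 percent untransformed / crop /
#' protected landscape with traces of settlement, timber and tree crops;
#' right-skewed Beta(1, 4) intensity in the four continuum classes; three
#' ecoregion bands, one a two-biome mosaic; 10 experts per combination with
#' sd 0.1 estimation noise around a truth table anchored at realistic
#' per-land-use intactness levels.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param nrow,ncol Landscape dimensions in pixels.
#' @param class_weights Named mixture weights over broad classes (sum 1).
#' @param theta Named list of per-class intensity distributions, each
#'   `list(type = "point", value =)`, `list(type = "uniform", min =, max =)`
#'   or `list(type = "beta", shape1 =, shape2 =)`.
#' @param ecoregions Data frame `ecoregion_id`, `share`, `biome1`, `biome2`.
#' @param groups Group ids to simulate scores and richness for (default
#'   [scenario_default_groups()]).
#' @param n_experts Experts per score combination.
#' @param expert_sd Standard deviation of expert estimation noise.
#' @param sampling Use multinomial class sampling and random theta draws
#'   instead of the deterministic quota/quantile construction.
#' @param species Parameters of the species-record generator: `n_species`,
#'   `category_effects`, `category_freq`, `beta_range`, `sigma_class`,
#'   `sigma_rg`, `sigma_resid`, `base`.
#' @return Object of class `bii_scenario`.
#' @export
bii_scenario <- function(seed = 1,
                         nrow = 40, ncol = 40,
                         class_weights = c(settlement = 0.004, timber = 0.003,
                                           tree_crop = 0.003, crop = 0.13,
                                           protected = 0.06,
                                           untransformed = 0.80),
                         theta = list(
                           settlement    = list(type = "beta", shape1 = 1, shape2 = 4),
                           tree_crop     = list(type = "beta", shape1 = 1, shape2 = 4),
                           crop          = list(type = "beta", shape1 = 1, shape2 = 4),
                           untransformed = list(type = "beta", shape1 = 1, shape2 = 4)),
                         ecoregions = data.frame(
                           ecoregion_id = c("eco1", "eco2", "eco3"),
                           share = c(0.4, 0.3, 0.3),
                           biome1 = c("grassland", "forest", "acacia_savanna"),
                           biome2 = c(NA, "grassland", NA),
                           stringsAsFactors = FALSE),
                         groups = NULL,
                         n_experts = 10, expert_sd = 0.1,
                         sampling = FALSE,
                         truth = NULL,
                         species = list()) {
  stopifnot(setequal(names(class_weights), .lu_classes))
  if (abs(sum(class_weights) - 1) > 1e-9)
    stop("class mixture weights must sum to 1")
  if (abs(sum(ecoregions$share) - 1) > 1e-9)
    stop("ecoregion shares must sum to 1")
  sp_defaults <- list(n_species = 500,
                      category_effects = c(LC = 0, NT = -0.05, VU = -0.10,
                                           EN = -0.15, CR = -0.30),
                      category_freq = c(LC = 0.60, NT = 0.10, VU = 0.12,
                                        EN = 0.10, CR = 0.05, DD = 0.025,
                                        EX = 0.005),
                      beta_range = 0.02, sigma_class = 0.05, sigma_rg = 0.05,
                      sigma_resid = 0.08, base = 0.7)
  species <- utils::modifyList(sp_defaults, species)
  if (!is.null(truth))
    stopifnot(all(c("group_id", "land_use", "biome", "truth") %in% names(truth)),
              all(truth$truth >= 0 & truth$truth <= 2))
  structure(list(seed = as.integer(seed), nrow = nrow, ncol = ncol,
                 class_weights = class_weights[.lu_classes], theta = theta,
                 ecoregions = ecoregions, groups = groups,
                 n_experts = n_experts, expert_sd = expert_sd,
                 sampling = sampling, truth = truth, species = species),
            class = "bii_scenario")
}

.scenario_groups <- function(scenario, registry) {
  if (is.null(scenario$groups)) scenario_default_groups(registry)
  else scenario$groups
}

## Theoretical mean of a theta distribution.
.theta_mean <- function(spec) {
  switch(spec$type,
         point = spec$value,
         uniform = (spec$min + spec$max) / 2,
         beta = spec$shape1 / (spec$shape1 + spec$shape2),
         stop("unknown theta distribution type '", spec$type, "'"))
}

## Midpoint-quantile draws (deterministic) or random draws.
.theta_draw <- function(spec, m, random = FALSE) {
  u <- if (random) stats::runif(m) else (seq_len(m) - 0.5) / m
  switch(spec$type,
         point = rep(spec$value, m),
         uniform = spec$min + u * (spec$max - spec$min),
         beta = stats::qbeta(u, spec$shape1, spec$shape2))
}

#' Ground-truth intactness table of a scenario
#'
#' Deterministic truth scores per (group, specific land use, biome for plant
#' groups): a realistic per-land-use base level plus a seeded group offset
#' (and a biome offset for plants), clipped to (0, 2).
#'
#' @param scenario A [bii_scenario()].
#' @param registry Group registry.
#' @return Data frame `group_id`, `land_use`, `biome`, `truth`. A truth table
#'   supplied in the scenario (`truth` element) is returned verbatim instead.
#' @export
scenario_truth <- function(scenario, registry = load_group_registry()) {
  if (!is.null(scenario$truth)) return(scenario$truth)
  base <- c("1a" = 0.45, "1b" = 0.20, "2" = 0.29, "3a4a" = 0.54,
            "3b" = 0.38, "4b" = 0.26, "5" = 0.95, "6a" = 0.85, "6b" = 0.51)
  groups <- .scenario_groups(scenario, registry)
  is_plant <- .is_plant_group(groups, registry)
  biomes <- unique(stats::na.omit(c(scenario$ecoregions$biome1,
                                    scenario$ecoregions$biome2)))
  .with_seed(scenario$seed + 101L, {
    g_off <- stats::setNames(stats::rnorm(length(groups), 0, 0.06), groups)
    rows <- lapply(groups, function(g) {
      bs <- if (is_plant[match(g, groups)]) biomes else NA_character_
      do.call(rbind, lapply(bs, function(b) {
        b_off <- if (is.na(b)) 0 else stats::rnorm(1, 0, 0.03)
        data.frame(group_id = g, land_use = names(base), biome = b,
                   truth = unname(pmin(1.98, pmax(0.02, base + g_off[g] + b_off))),
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate expert score records
#'
#' Each expert's score is `clip(truth + Normal(0, sd), 0, 2)`, independent
#' across experts and combinations, with `n_experts` experts per
#' combination.
#'
#' @param scenario A [bii_scenario()].
#' @param registry Group registry.
#' @param noise_seed Optional seed for the expert-noise stream only, so
#'   replicate studies can redraw noise while keeping the scenario (and its
#'   truth table) fixed. Defaults to a stream derived from the scenario seed.
#' @return Score records as from [read_score_table()].
#' @export
simulate_expert_scores <- function(scenario, registry = load_group_registry(),
                                   noise_seed = NULL) {
  truth <- scenario_truth(scenario, registry)
  n <- scenario$n_experts
  if (is.null(noise_seed)) noise_seed <- scenario$seed + 202L
  .with_seed(noise_seed, {
    rec <- truth[rep(seq_len(nrow(truth)), each = n), ]
    rec$expert_id <- paste0("e", rep(seq_len(n), times = nrow(truth)))
    rec$score <- pmin(2, pmax(0, rec$truth +
                                stats::rnorm(nrow(rec), 0, scenario$expert_sd)))
    rec <- rec[, c("expert_id", "group_id", "land_use", "biome", "score")]
    rownames(rec) <- NULL
    rec
  })
}

#' Simulate per-ecoregion richness tables
#'
#' Vertebrate richness is a seeded Poisson count per (ecoregion, group);
#' plant richness comes from seeded biome-level group proportions multiplied
#' by a seeded total vascular-plant richness per ecoregion (mosaics
#' averaged, renormalised), via [plant_richness()].
#'
#' @param scenario A [bii_scenario()].
#' @param registry Group registry.
#' @return List with `richness` (table over all scenario groups),
#'   `biome_proportions` and `total_richness`.
#' @export
simulate_richness <- function(scenario, registry = load_group_registry()) {
  groups <- .scenario_groups(scenario, registry)
  cls <- registry$taxon_class[match(groups, registry$group_id)]
  vg <- groups[cls %in% .vertebrate_classes]
  pg <- groups[cls %in% .plant_classes]
  eco <- scenario$ecoregions
  lambda <- c(amphibian = 8, reptile = 10, bird = 25, mammal = 12)
  .with_seed(scenario$seed + 303L, {
    vert <- do.call(rbind, lapply(eco$ecoregion_id, function(e) {
      lam <- lambda[registry$taxon_class[match(vg, registry$group_id)]]
      n <- 1 + stats::rpois(length(vg), lam)
      data.frame(ecoregion_id = e, group_id = vg, richness = n,
                 stringsAsFactors = FALSE)
    }))
    out <- list()
    if (length(pg)) {
      biomes <- unique(stats::na.omit(c(eco$biome1, eco$biome2)))
      props <- do.call(rbind, lapply(biomes, function(b) {
        w <- stats::rgamma(length(pg), shape = 4)
        data.frame(biome = b, group_id = pg, proportion = w / sum(w),
                   stringsAsFactors = FALSE)
      }))
      totals <- data.frame(ecoregion_id = eco$ecoregion_id,
                           total = round(stats::runif(nrow(eco), 1500, 4000)))
      plants <- plant_richness(props, totals, eco)
      out <- list(richness = rbind(vert, plants),
                  biome_proportions = props, total_richness = totals)
    } else {
      out <- list(richness = vert, biome_proportions = NULL,
                  total_richness = NULL)
    }
    out
  })
}

#' Simulate a land-use landscape with known composition
#'
#' Ecoregions occupy contiguous pixel runs with exact-quota sizes; within
#' each ecoregion, classes get exact-quota pixel counts and continuum
#' classes receive intensities at midpoint quantiles of their configured
#' distribution (deterministic), or multinomial classes and random draws
#' when the scenario's `sampling` flag is set.
#'
#' @param scenario A [bii_scenario()].
#' @return List with `lu` ([land_use_grid()]), `ecoregions` (id matrix) and
#'   `ecoregion_biomes` (data frame for mosaic resolution).
#' @export
simulate_landscape <- function(scenario) {
  N <- scenario$nrow * scenario$ncol
  eco_n <- quota_counts(N, stats::setNames(scenario$ecoregions$share,
                                           scenario$ecoregions$ecoregion_id))
  eco_vec <- rep(scenario$ecoregions$ecoregion_id, times = eco_n)
  cls_vec <- character(N)
  th_vec <- rep(NA_real_, N)
  pos <- 0L
  draw <- function(spec, m) .theta_draw(spec, m, random = scenario$sampling)
  body <- function() {
    for (i in seq_along(eco_n)) {
      n_e <- eco_n[i]
      counts <- if (scenario$sampling)
        stats::setNames(as.vector(stats::rmultinom(1, n_e, scenario$class_weights)),
                        names(scenario$class_weights))
      else quota_counts(n_e, scenario$class_weights)
      for (k in names(counts)) {
        m <- counts[[k]]
        if (m == 0) next
        idx <- pos + seq_len(m)
        cls_vec[idx] <<- k
        if (.lu_has_intensity[k]) th_vec[idx] <<- draw(scenario$theta[[k]], m)
        pos <<- pos + m
      }
    }
  }
  if (scenario$sampling) .with_seed(scenario$seed + 404L, body()) else body()
  lu <- land_use_grid(matrix(cls_vec, scenario$nrow, scenario$ncol),
                      matrix(th_vec, scenario$nrow, scenario$ncol))
  list(lu = lu,
       ecoregions = matrix(eco_vec, scenario$nrow, scenario$ncol),
       ecoregion_biomes = scenario$ecoregions[, c("ecoregion_id", "biome1",
                                                  "biome2")])
}

#' Closed-form expected BII of a deterministic scenario landscape
#'
#' Computes the expectation analytically from the truth table and richness:
#' for each ecoregion and class, the richness-weighted truth intactness at
#' the low and high intensity endpoints, combined linearly at the mean of
#' the class's intensity distribution (the interpolation is linear in theta,
#' so only the mean enters), then averaged over the exact-quota class and
#' ecoregion composition. This is the independent oracle for the full
#' pipeline; it never calls the map engine.
#'
#' @param scenario A [bii_scenario()].
#' @param richness Richness table (e.g. from [simulate_richness()]).
#' @param registry Group registry.
#' @param subset Group subset as in [bii_map()].
#' @return Expected regional mean BII (fraction).
#' @export
expected_bii <- function(scenario, richness, registry = load_group_registry(),
                         subset = "all") {
  truth <- scenario_truth(scenario, registry)
  groups <- intersect(.subset_groups(subset, registry),
                      .scenario_groups(scenario, registry))
  eco <- scenario$ecoregions
  N <- scenario$nrow * scenario$ncol
  eco_n <- quota_counts(N, stats::setNames(eco$share, eco$ecoregion_id))
  truth_of <- function(g, code, b1, b2) {
    pick <- function(b) {
      t <- truth$truth[truth$group_id == g & truth$land_use == code &
                       (is.na(b) & is.na(truth$biome) |
                        !is.na(truth$biome) & !is.na(b) & truth$biome == b)]
      if (!length(t)) stop("truth missing for ", g, " / ", code)
      t
    }
    if (.is_plant_group(g, registry)) {
      if (is.na(b2)) pick(b1) else (pick(b1) + pick(b2)) / 2
    } else pick(NA)
  }
  total <- 0; total_n <- 0
  for (i in seq_len(nrow(eco))) {
    e <- eco$ecoregion_id[i]
    r <- richness[richness$ecoregion_id == e & richness$group_id %in% groups &
                  richness$richness > 0, ]
    if (!nrow(r)) next
    counts <- quota_counts(eco_n[[i]], scenario$class_weights)
    for (k in names(counts)) {
      if (counts[[k]] == 0) next
      ep <- .lu_endpoints[.lu_endpoints$class == k, ]
      s_lo <- sum(r$richness * vapply(r$group_id, truth_of, 0, code = ep$low,
                                      b1 = eco$biome1[i], b2 = eco$biome2[i])) /
        sum(r$richness)
      s_hi <- sum(r$richness * vapply(r$group_id, truth_of, 0, code = ep$high,
                                      b1 = eco$biome1[i], b2 = eco$biome2[i])) /
        sum(r$richness)
      mth <- if (.lu_has_intensity[k]) .theta_mean(scenario$theta[[k]]) else 0
      total <- total + counts[[k]] * ((1 - mth) * s_lo + mth * s_hi)
      total_n <- total_n + counts[[k]]
    }
  }
  if (total_n == 0) stop("no defined pixels for this subset")
  total / total_n
}

#' Simulate species records for the threat-category model
#'
#' Generates one record per species: a range-wide BII built from a class
#' intercept, a functional-group intercept nested in class, an IUCN-category
#' effect, a scaled-range-size effect and Gaussian noise; categories are
#' assigned with the configured frequencies (including DD and EX records,
#' which the model must exclude).
#'
#' @param scenario A [bii_scenario()]; see the `species` element.
#' @param registry Group registry.
#' @return Data frame suitable for [threat_category_model()], with the true
#'   generating effects attached as attribute `truth`.
#' @export
simulate_species_records <- function(scenario, registry = load_group_registry()) {
  sp <- scenario$species
  .with_seed(scenario$seed + 505L, {
    classes <- .vertebrate_classes
    rg_pool <- registry[registry$taxon_class %in% classes &
                        !registry$species_level, ]
    n <- sp$n_species
    cls <- sample(classes, n, replace = TRUE)
    rg <- vapply(cls, function(cc)
      sample(rg_pool$group_id[rg_pool$taxon_class == cc], 1), "")
    cat <- sample(names(sp$category_freq), n, replace = TRUE,
                  prob = sp$category_freq)
    u_class <- stats::setNames(stats::rnorm(length(classes), 0, sp$sigma_class),
                               classes)
    u_rg <- stats::setNames(stats::rnorm(nrow(rg_pool), 0, sp$sigma_rg),
                            rg_pool$group_id)
    range_size <- stats::rlnorm(n, meanlog = 10, sdlog = 1.5)
    z <- as.numeric(scale(log(range_size)))
    eff <- ifelse(cat %in% names(sp$category_effects),
                  sp$category_effects[cat], 0)
    bii <- sp$base + u_class[cls] + u_rg[rg] + eff + sp$beta_range * z +
      stats::rnorm(n, 0, sp$sigma_resid)
    out <- data.frame(species_id = paste0("sp", seq_len(n)), class = cls,
                      group_id = rg, bii = as.numeric(bii),
                      iucn_category = cat, range_size = range_size,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "truth") <- sp
    out
  })
}

#' Simulate pressure layers consistent with a landscape
#'
#' Builds the proxy layers the allocation decision tree and intensity
#' protocol consume (population density, land-cover fractions, protection
#' mask, livestock density, nitrogen input, field size, rainfall, soil
#' class), constructed so that [allocate_land_use()] under the default
#' configuration recovers the landscape's classes exactly.
#'
#' @param scenario A [bii_scenario()].
#' @param landscape Output of [simulate_landscape()].
#' @return Named list of layers (numeric matrices; `soil` is character).
#' @export
simulate_pressure_layers <- function(scenario, landscape) {
  lu <- landscape$lu
  cls <- lu$class
  th <- lu$intensity
  dims <- dim(cls)
  .with_seed(scenario$seed + 606L, {
    ru <- function(max) matrix(stats::runif(prod(dims), 0, max), dims[1], dims[2])
    pop <- ru(900)
    pop[cls == "settlement"] <- 1000 + 9000 * th[cls == "settlement"]
    cover <- function(k) { m <- ru(0.4); m[cls == k] <- 0.8; m }
    nitro <- ru(20); nitro[cls == "crop"] <- 100 * th[cls == "crop"]
    fs <- ru(1); fs[cls == "crop"] <- 10 * th[cls == "crop"]
    lsd <- ru(5)
    lsd[cls == "untransformed"] <- 200 * th[cls == "untransformed"]
    list(population_density = pop,
         timber_cover = cover("timber"),
         tree_crop_cover = cover("tree_crop"),
         crop_cover = cover("crop"),
         protected_strict = matrix(as.numeric(cls == "protected"),
                                   dims[1], dims[2]),
         nitrogen_input = nitro,
         field_size = fs,
         livestock_density = lsd,
         mar = ru(1600),
         soil = matrix(sample(c("high", "medium", "low"), prod(dims),
                              replace = TRUE), dims[1], dims[2]))
  })
}
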