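# The synthetic-data generators and their closed-form expectations.

test_that("generators are pure functions of the scenario seed", {
  reg <- load_group_registry()
  sc <- bii_scenario(seed = 61)
  expect_identical(simulate_expert_scores(sc, reg),
                   simulate_expert_scores(sc, reg))
  expect_identical(simulate_landscape(sc), simulate_landscape(sc))
  expect_identical(simulate_richness(sc, reg), simulate_richness(sc, reg))
  expect_identical(simulate_species_records(sc, reg),
                   simulate_species_records(sc, reg))
  # generators do not disturb the session RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_expert_scores(sc, reg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless experts return the truth verbatim", {
  reg <- load_group_registry()
  sc <- bii_scenario(seed = 62, expert_sd = 0, n_experts = 3)
  rec <- simulate_expert_scores(sc, reg)
  truth <- scenario_truth(sc, reg)
  agg <- aggregate_scores(rec)
  key <- function(d) paste(d$group_id, d$land_use, d$biome)
  expect_equal(agg$mean[match(key(truth), key(agg))], truth$truth)
  expect_equal(agg$ci_upper - agg$ci_lower, rep(0, nrow(agg)))
})

test_that("aggregated means converge to truth by the law of large numbers", {
  reg <- load_group_registry()
  sc <- bii_scenario(seed = 63, groups = c("amp01", "rep01"),
                     n_experts = 10000, expert_sd = 0.1)
  agg <- aggregate_scores(simulate_expert_scores(sc, reg))
  truth <- scenario_truth(sc, reg)
  key <- function(d) paste(d$group_id, d$land_use, d$biome)
  err <- abs(agg$mean[match(key(truth), key(agg))] - truth$truth)
  expect_lt(max(err), 0.005)
})

test_that("exact-quota composition is exact and validated", {
  expect_equal(quota_counts(100, c(a = 0.25, b = 0.75)), c(a = 25L, b = 75L))
  expect_equal(sum(quota_counts(97, c(a = 1 / 3, b = 1 / 3, c = 1 / 3))), 97)
  expect_error(quota_counts(10, c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(bii_scenario(class_weights = c(settlement = 1, timber = 1,
                                              tree_crop = 0, crop = 0,
                                              protected = 0, untransformed = 0)),
               "sum to 1")

  sc <- bii_scenario(seed = 64, nrow = 25, ncol = 40)
  ls <- simulate_landscape(sc)
  comp <- table(ls$lu$class) / 1000
  expect_equal(comp[["untransformed"]], 0.80)
  expect_equal(comp[["crop"]], 0.13)
  expect_equal(comp[["protected"]], 0.06)
})

test_that("degenerate scenarios have the obvious expectations", {
  reg <- tiny_registry()
  truth <- flat_scores(1.0)[, c("group_id", "land_use", "biome")]
  truth$truth <- 1.0
  all_protected <- bii_scenario(
    seed = 65, nrow = 4, ncol = 4,
    class_weights = c(settlement = 0, timber = 0, tree_crop = 0, crop = 0,
                      protected = 1, untransformed = 0),
    ecoregions = data.frame(ecoregion_id = "e1", share = 1,
                            biome1 = "grassland", biome2 = NA),
    groups = reg$group_id, truth = truth)
  rich <- flat_richness("e1", reg)
  expect_equal(expected_bii(all_protected, rich, reg), 1.0)

  # 50/50 low/high-intensity crop: expectation is the endpoint midpoint
  truth2 <- truth
  truth2$truth[truth2$land_use == "3a4a"] <- 0.54
  truth2$truth[truth2$land_use == "4b"] <- 0.26
  crop_sc <- bii_scenario(
    seed = 66, nrow = 4, ncol = 4,
    class_weights = c(settlement = 0, timber = 0, tree_crop = 0, crop = 1,
                      protected = 0, untransformed = 0),
    theta = list(crop = list(type = "uniform", min = 0, max = 1)),
    ecoregions = data.frame(ecoregion_id = "e1", share = 1,
                            biome1 = "grassland", biome2 = NA),
    groups = reg$group_id, truth = truth2)
  expect_equal(expected_bii(crop_sc, rich, reg), (0.54 + 0.26) / 2)
})

test_that("right-skewed intensity raises expected BII when low beats high", {
  reg <- tiny_registry()
  rich <- flat_richness("e1", reg)
  mk <- function(theta_spec) bii_scenario(
    seed = 67, nrow = 10, ncol = 10,
    class_weights = c(settlement = 0, timber = 0, tree_crop = 0, crop = 0,
                      protected = 0, untransformed = 1),
    theta = list(untransformed = theta_spec),
    ecoregions = data.frame(ecoregion_id = "e1", share = 1,
                            biome1 = "grassland", biome2 = NA),
    groups = reg$group_id)
  skewed <- expected_bii(mk(list(type = "beta", shape1 = 1, shape2 = 4)),
                         rich, reg)
  flat <- expected_bii(mk(list(type = "uniform", min = 0, max = 1)), rich, reg)
  # default truth has near-natural (6a) above rangeland (6b)
  expect_gt(skewed, flat)
})

test_that("the pipeline reproduces the analytic expectation", {
  reg <- load_group_registry()
  run <- function(sc) {
    ls <- simulate_landscape(sc)
    rich <- simulate_richness(sc, reg)
    agg <- aggregate_scores(simulate_expert_scores(sc, reg))
    map <- bii_map(ls$lu, ls$ecoregions, rich$richness, agg, reg, "all",
                   ls$ecoregion_biomes)
    list(got = zonal_bii(map)$mean,
         want = expected_bii(sc, rich$richness, reg))
  }
  # point-mass intensities: agreement to numerical precision
  pt <- bii_scenario(seed = 68, expert_sd = 0,
                     theta = list(settlement = list(type = "point", value = 0.4),
                                  tree_crop = list(type = "point", value = 0.8),
                                  crop = list(type = "point", value = 0.1),
                                  untransformed = list(type = "point", value = 0.3)))
  r <- run(pt)
  expect_equal(r$got, r$want, tolerance = 1e-9)

  # uniform intensities: midpoint quantiles reproduce the mean exactly
  un <- bii_scenario(seed = 69, expert_sd = 0,
                     theta = list(settlement = list(type = "uniform", min = 0, max = 1),
                                  tree_crop = list(type = "uniform", min = 0.2, max = 0.6),
                                  crop = list(type = "uniform", min = 0, max = 1),
                                  untransformed = list(type = "uniform", min = 0, max = 0.5)))
  r2 <- run(un)
  expect_equal(r2$got, r2$want, tolerance = 1e-9)

  # Beta intensities: agreement up to quantile-discretisation error
  be <- bii_scenario(seed = 70, expert_sd = 0, nrow = 60, ncol = 60)
  r3 <- run(be)
  expect_equal(r3$got, r3$want, tolerance = 1e-3)
})

test_that("species records degenerate correctly and reproduce", {
  reg <- load_group_registry()
  sc <- bii_scenario(seed = 71, species = list(
    n_species = 50, sigma_class = 0, sigma_rg = 0, sigma_resid = 0,
    beta_range = 0,
    category_effects = c(LC = 0, NT = 0, VU = 0, EN = 0, CR = 0)))
  recs <- simulate_species_records(sc, reg)
  expect_equal(unique(recs$bii), attr(recs, "truth")$base)
})

test_that("simulated pressure layers let allocation recover the landscape", {
  sc <- bii_scenario(seed = 72, nrow = 20, ncol = 20)
  ls <- simulate_landscape(sc)
  prox <- simulate_pressure_layers(sc, ls)
  lu2 <- allocate_land_use(prox)
  expect_identical(lu2$class, ls$lu$class)
  # and the intensity protocol produces valid theta on every continuum pixel
  lu3 <- compute_intensity(lu2, prox)
  cont <- has_intensity(as.vector(lu3$class))
  expect_true(all(!is.na(lu3$intensity[matrix(cont, 20, 20)])))
})

test_that("generated tables round-trip through the package formats", {
  reg <- load_group_registry()
  sc <- bii_scenario(seed = 73, nrow = 6, ncol = 6)
  ls <- simulate_landscape(sc)
  dir <- withr::local_tempdir()

  gpath <- file.path(dir, "classes.csv")
  write_grid_csv(ls$lu$class, gpath, ls$lu$geom)
  back <- read_grid_csv(gpath, "character")
  expect_equal(unclass(back), unclass(ls$lu$class), ignore_attr = TRUE)
  expect_equal(attr(back, "geom")$nrow, 6)

  rec <- simulate_expert_scores(sc, reg)
  spath <- file.path(dir, "scores.csv")
  write.csv(rec, spath, row.names = FALSE)
  rec2 <- read_score_table(spath, registry = reg)
  expect_equal(rec2$score, rec$score)
  expect_equal(rec2$biome, rec$biome)
})
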