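# Corroboration statistics: Spearman, Mann-Whitney, threat-category model.

test_that("spearman correlation handles monotone data, ties and constants", {
  d <- data.frame(bii_mean = c(1, 2, 3, 4, 5), hfi = c(2, 4, 6, 8, 10))
  expect_equal(spearman_vs_index(d, "hfi")$rho, 1)
  d$hfi <- rev(d$hfi)
  expect_equal(spearman_vs_index(d, "hfi")$rho, -1)

  # tied toy data against the hand-rank (average-rank Pearson) formula
  d2 <- data.frame(bii_mean = c(0.3, 0.5, 0.5, 0.8, 0.9),
                   bmi = c(7, 7, 3, 2, 1))
  hand <- cor(rank(d2$bii_mean), rank(d2$bmi))
  expect_equal(spearman_vs_index(d2, "bmi")$rho, hand, tolerance = 1e-12)

  cst <- data.frame(bii_mean = c(1, 1, 1), bhi = c(1, 2, 3))
  expect_false(spearman_vs_index(cst, "bhi")$defined)
  expect_error(spearman_vs_index(d[1:2, ], "hfi"), "at least 3")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(51)
  d <- data.frame(bii_mean = runif(20), hfi = runif(20))
  base <- spearman_vs_index(d, "hfi")$rho
  d2 <- d; d2$bii_mean <- exp(3 * d2$bii_mean); d2$hfi <- d2$hfi^3 - 5
  expect_equal(spearman_vs_index(d2, "hfi")$rho, base, tolerance = 1e-12)
})

test_that("exact Mann-Whitney p equals full enumeration", {
  # canonical example: complete separation of {1,2} vs {3,4}
  res <- mann_whitney_u(c(1, 2), c(3, 4), method = "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)

  # independent enumeration oracle over random pooled sets (with ties)
  enum_p <- function(x, y) {
    pool <- c(x, y); n1 <- length(x); n <- length(pool)
    u_of <- function(a, b) sum(rank(c(a, b))[seq_along(a)]) -
      length(a) * (length(a) + 1) / 2
    obs <- min(u_of(x, y), n1 * length(y) - u_of(x, y))
    sets <- combn(n, n1)
    us <- apply(sets, 2, function(i) u_of(pool[i], pool[-i]))
    mean(pmin(us, n1 * length(y) - us) <= obs + 1e-9)
  }
  set.seed(52)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    pool <- sample(1:4, n1 + n2, replace = TRUE)  # forces ties
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y, method = "exact")$p_value,
                 enum_p(x, y))
  }
})

test_that("normal approximation tracks the exact test at moderate n", {
  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    pe <- mann_whitney_u(x, y, method = "exact")$p_value
    pn <- mann_whitney_u(x, y, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  # tie-free cross-check against the standard implementation
  x <- c(1.2, 3.4, 0.5, 7.1); y <- c(2.2, 5.5, 6.1, 0.1, 4.4)
  expect_equal(mann_whitney_u(x, y, method = "exact")$U,
               unname(wilcox.test(x, y)$statistic))
  expect_equal(mann_whitney_u(x, y, method = "exact")$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("identical strata give p of 1 and hotspots need both groups", {
  d <- data.frame(bii_mean = rep(c(0.5, 0.7), 4),
                  hotspot_flag = rep(c(TRUE, FALSE), each = 4))
  d$bii_mean <- rep(c(0.5, 0.7, 0.6, 0.8), 2)  # same values in both strata
  res <- hotspot_test(d)
  expect_gte(res$p_value, 0.99)
  expect_error(hotspot_test(data.frame(bii_mean = 1:3, hotspot_flag = TRUE)),
               "non-empty")
})

test_that("hotspot ecoregions with genuinely lower BII are detected", {
  set.seed(54)
  d <- data.frame(bii_mean = c(runif(12, 0.3, 0.6), runif(12, 0.6, 0.95)),
                  hotspot_flag = rep(c(TRUE, FALSE), each = 12))
  res <- hotspot_test(d)
  expect_equal(res$method, "normal")
  expect_lt(res$p_value, 0.01)
  expect_lt(res$median_hotspot, res$median_other)
})

test_that("the threat-category model recovers simulated effects within 2 SE", {
  reg <- load_group_registry()
  sc <- bii_scenario(seed = 55, species = list(n_species = 500))
  recs <- simulate_species_records(sc, reg)
  fit <- threat_category_model(recs)
  truth <- attr(recs, "truth")$category_effects
  fe <- fit$fixed_effects
  for (cat in c("NT", "VU", "EN", "CR")) {
    row <- fe[fe$term == paste0("iucn_category", cat), ]
    expect_lt(abs(row$estimate - truth[[cat]]), 2 * row$se)
  }
  expect_equal(fit$n_excluded_dd + fit$n_excluded_ex,
               sum(recs$iucn_category %in% c("DD", "EX")))
  expect_equal(fit$n_used, nrow(recs) - fit$n_excluded_dd - fit$n_excluded_ex)
  # strong simulated effects: the omnibus test must reject
  expect_lt(fit$omnibus$p_value, 1e-6)
  # Tukey contrasts cover all 10 category pairs
  expect_equal(nrow(fit$contrasts), 10)
})

test_that("category-effect estimates are unbiased across replicates", {
  reg <- load_group_registry()
  ests <- vapply(1:100, function(i) {
    sc <- bii_scenario(seed = 1000 + i, species = list(n_species = 1000))
    recs <- simulate_species_records(sc, reg)
    fit <- suppressWarnings(suppressMessages(threat_category_model(recs)))
    fe <- fit$fixed_effects
    fe$estimate[fe$term == "iucn_categoryCR"]
  }, 0)
  expect_lt(abs(mean(ests) - (-0.30)), 0.1 * 0.30)
})

test_that("omnibus p-values are uniform under the null", {
  reg <- load_group_registry()
  null_effects <- c(LC = 0, NT = 0, VU = 0, EN = 0, CR = 0)
  ps <- vapply(1:200, function(i) {
    sc <- bii_scenario(seed = 5000 + i,
                       species = list(n_species = 250,
                                      category_effects = null_effects))
    recs <- simulate_species_records(sc, reg)
    fit <- suppressWarnings(suppressMessages(threat_category_model(recs)))
    fit$omnibus$p_value
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
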