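## Corroboration statistics.
##
## Three checks of the assessment against external information: Spearman
## rank correlations of ecoregion-mean BII against external pressure indices
## (HFI, BMI, BHI), a two-sided Mann-Whitney comparison of hotspot vs
## non-hotspot ecoregions, and a Gaussian mixed-effects model testing
## whether IUCN threat category predicts a species' range-wide BII:
##
##   bii ~ iucn_category + range_scaled + (1 | class / group_id)

#' Spearman rank correlation of BII against an external index
#'
#' Average-rank ties; two-sided p-value. A constant vector yields an
#' undefined correlation, flagged rather than erroring.
#'
#' @param summary Data frame of ecoregion summaries containing `bii_mean`
#'   and the index column.
#' @param index_name Name of the index column (e.g. `"hfi"`).
#' @return List with `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_vs_index <- function(summary, index_name) {
  stopifnot("bii_mean" %in% names(summary), index_name %in% names(summary))
  x <- summary$bii_mean; y <- summary[[index_name]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       defined = TRUE)
}

## U statistic counting pairs where x beats y (ties count 1/2).
.mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test with average-rank tie handling. For a
#' combined sample size up to `exact_limit` the p-value is computed exactly
#' by enumerating every assignment of the pooled values to the two groups
#' (extremeness measured by `min(U, n1*n2 - U)`, which handles ties
#' correctly); otherwise a tie-corrected normal approximation with
#' continuity correction is used. Both methods can be forced.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param method `"auto"`, `"exact"`, or `"normal"`.
#' @param exact_limit Combined-size switch point for `"auto"` (default 12).
#' @return List with `U`, `p_value`, `method`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           exact_limit = 12) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  U <- .mw_u(x, y)
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "normal"
  if (method == "exact") {
    pool <- c(x, y)
    obs <- min(U, n1 * n2 - U)
    sets <- utils::combn(n, n1)
    us <- apply(sets, 2, function(idx) .mw_u(pool[idx], pool[-idx]))
    p <- mean(pmin(us, n1 * n2 - us) <= obs + 1e-9)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = method,
                                 n1 = n1, n2 = n2))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Compare BII of hotspot vs other ecoregions
#'
#' Two-sided Mann-Whitney U test of ecoregion-mean BII between biodiversity
#' hotspots (flagged by the >= 50% areal-overlap rule upstream) and all
#' other ecoregions. Hotspots are expected to rank lower.
#'
#' @param summary Data frame with columns `bii_mean` and logical
#'   `hotspot_flag`.
#' @param method Passed to [mann_whitney_u()].
#' @return List as from [mann_whitney_u()], plus the two group medians.
#' @export
hotspot_test <- function(summary, method = "auto") {
  stopifnot(all(c("bii_mean", "hotspot_flag") %in% names(summary)))
  hs <- summary$bii_mean[summary$hotspot_flag]
  other <- summary$bii_mean[!summary$hotspot_flag]
  if (!length(hs) || !length(other))
    stop("both hotspot and non-hotspot strata must be non-empty")
  res <- mann_whitney_u(hs, other, method = method)
  res$median_hotspot <- stats::median(hs)
  res$median_other <- stats::median(other)
  res
}

#' Mixed-effects model of BII against IUCN threat category
#'
#' Fits the Gaussian linear mixed model
#' `bii ~ iucn_category + range_scaled + (1 | class/group_id)` by REML, with
#' random intercepts for taxonomic class and functional response group
#' nested in class. Data-deficient (DD) and extinct (EX) species are
#' excluded and counted. Range size is scaled and centred. The category
#' effect is tested with a Satterthwaite omnibus F test, and all pairwise
#' category contrasts are reported with Tukey adjustment. LC (least concern)
#' is the reference level.
#'
#' @param records Data frame with columns `species_id`, `class`, `group_id`,
#'   `bii`, `iucn_category` (over CR, EN, VU, NT, LC, DD, EX), `range_size`.
#' @return List with elements `fit`, `fixed_effects`, `omnibus` (F, df,
#'   p_value), `contrasts`, `n_used`, `n_excluded_dd`, `n_excluded_ex`,
#'   `singular`.
#' @export
threat_category_model <- function(records) {
  need <- c("species_id", "class", "group_id", "bii", "iucn_category",
            "range_size")
  stopifnot(all(need %in% names(records)))
  n_dd <- sum(records$iucn_category == "DD")
  n_ex <- sum(records$iucn_category == "EX")
  d <- records[!records$iucn_category %in% c("DD", "EX"), , drop = FALSE]
  d$iucn_category <- factor(d$iucn_category,
                            levels = c("LC", "NT", "VU", "EN", "CR"))
  d$iucn_category <- droplevels(d$iucn_category)
  if (nlevels(d$iucn_category) < 2)
    stop("need at least 2 IUCN categories to fit the model")
  d$range_scaled <- as.numeric(scale(d$range_size))
  fit <- lmerTest::lmer(bii ~ iucn_category + range_scaled +
                          (1 | class / group_id),
                        data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular mixed-model fit: a variance component is estimated at 0")
  an <- stats::anova(fit)  # Satterthwaite type III
  omn <- list(F = an["iucn_category", "F value"],
              df1 = an["iucn_category", "NumDF"],
              df2 = an["iucn_category", "DenDF"],
              p_value = an["iucn_category", "Pr(>F)"])
  co <- summary(fit)$coefficients
  emm <- emmeans::emmeans(fit, "iucn_category", lmer.df = "satterthwaite")
  contrasts <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                               adjust = "tukey"))
  list(fit = fit,
       fixed_effects = data.frame(term = rownames(co),
                                  estimate = co[, "Estimate"],
                                  se = co[, "Std. Error"],
                                  row.names = NULL),
       omnibus = omn, contrasts = contrasts,
       n_used = nrow(d), n_excluded_dd = n_dd, n_excluded_ex = n_ex,
       singular = singular)
}
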