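## Expert intactness-score tables: reading, validation, aggregation.
##
## Each record is one expert's estimate of the remaining fraction of a
## functional response group's reference abundance under one specific land
## use (and, for plant groups, one biome). Scores live in [0, 2]: 0 = no
## remaining individuals, 1 = reference abundance, up to 2 for groups that
## thrive under human modification.

#' Default column mapping for score tables
#'
#' Maps the canonical record fields to column names in a delimited score
#' table. The default matches the bundled synthetic fixtures; override any
#' entry to read other layouts.
#'
#' @param expert,group,land_use,biome,score Column names in the input table.
#' @return Named list used as the `schema` of [read_score_table()].
#' @export
score_schema <- function(expert = "expert_id", group = "group_id",
                         land_use = "land_use", biome = "biome",
                         score = "score") {
  list(expert = expert, group = group, land_use = land_use,
       biome = biome, score = score)
}

#' Read and validate an expert score table
#'
#' Reads a delimited table (or accepts a data frame) of per-expert intactness
#' scores, validates land-use codes and the \[0, 2\] score bound, drops rows
#' with blank score cells (counting them in a load report) and checks record
#' uniqueness. When a functional-group registry is supplied, the rule that a
#' biome is present iff the group is a plant group is enforced.
#'
#' @param source Path to a CSV/TSV file or a data frame.
#' @param schema Column mapping from [score_schema()].
#' @param registry Optional group registry (see [load_group_registry()]) used
#'   to validate biome presence.
#' @return Data frame with columns `expert_id`, `group_id`, `land_use`,
#'   `biome`, `score`; attribute `load_report` records dropped blank rows.
#' @export
read_score_table <- function(source, schema = score_schema(), registry = NULL) {
  tab <- if (is.data.frame(source)) source else {
    sep <- if (grepl("\\.tsv$", source, ignore.case = TRUE)) "\t" else ","
    utils::read.table(source, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  }
  need <- unlist(schema[c("expert", "group", "land_use", "score")])
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("score table lacks column(s): ", paste(missing_cols, collapse = ", "))
  rec <- data.frame(
    expert_id = as.character(tab[[schema$expert]]),
    group_id  = as.character(tab[[schema$group]]),
    land_use  = as.character(tab[[schema$land_use]]),
    biome     = if (schema$biome %in% names(tab))
                  as.character(tab[[schema$biome]]) else NA_character_,
    score     = suppressWarnings(as.numeric(tab[[schema$score]])),
    stringsAsFactors = FALSE
  )
  rec$biome[!is.na(rec$biome) & rec$biome == ""] <- NA_character_

  blank <- is.na(tab[[schema$score]]) | trimws(as.character(tab[[schema$score]])) == ""
  n_blank <- sum(blank)
  rec <- rec[!blank, , drop = FALSE]

  bad_lu <- setdiff(unique(rec$land_use), .lu_codes$code)
  if (length(bad_lu))
    stop("unknown land-use code(s): ", paste(bad_lu, collapse = ", "),
         "; valid codes are: ", paste(.lu_codes$code, collapse = ", "))
  out_of_range <- which(is.na(rec$score) | rec$score < 0 | rec$score > 2)
  if (length(out_of_range))
    stop("score outside [0, 2] at row(s): ",
         paste(utils::head(out_of_range, 10), collapse = ", "))

  if (!is.null(registry)) {
    is_plant <- registry$taxon_class[match(rec$group_id, registry$group_id)] %in%
      .plant_classes
    if (anyNA(match(rec$group_id, registry$group_id)))
      stop("group(s) not in registry: ",
           paste(unique(rec$group_id[is.na(match(rec$group_id, registry$group_id))]),
                 collapse = ", "))
    if (any(is_plant & is.na(rec$biome)))
      stop("plant-group records must carry a biome")
    if (any(!is_plant & !is.na(rec$biome)))
      stop("non-plant records must not carry a biome")
  }

  key <- paste(rec$expert_id, rec$group_id, rec$land_use, rec$biome, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (expert, group, land use, biome) record(s)")
  rownames(rec) <- NULL
  attr(rec, "load_report") <- list(n_records = nrow(rec), n_blank_dropped = n_blank)
  rec
}

## stable combination key; \r never occurs in identifiers
.combo_key <- function(records)
  paste(records$group_id, records$land_use, records$biome, sep = "\r")

#' Aggregate expert scores into means with confidence bounds
#'
#' For every (group, land use, biome) combination, computes the arithmetic
#' mean across experts and a Student-t confidence interval
#' `mean +/- t * sd / sqrt(n)`, clipped to the \[0, 2\] score domain.
#' Combinations scored by a single expert get a degenerate interval equal to
#' the mean and are flagged.
#'
#' @param records Score records from [read_score_table()].
#' @param ci_level Confidence level (default 0.95).
#' @return Data frame with columns `group_id`, `land_use`, `biome`, `mean`,
#'   `ci_lower`, `ci_upper`, `n_experts`, `single_expert`; empty input gives
#'   an empty table.
#' @export
aggregate_scores <- function(records, ci_level = 0.95) {
  stopifnot(ci_level > 0, ci_level < 1)
  empty <- data.frame(group_id = character(), land_use = character(),
                      biome = character(), mean = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      n_experts = integer(), single_expert = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  key <- .combo_key(records)
  f <- factor(key)
  n <- as.integer(table(f))
  m <- as.vector(rowsum(records$score, f)) / n
  ## two-pass (centred) variance: stable when experts agree exactly
  ss <- as.vector(rowsum((records$score - m[as.integer(f)])^2, f))
  sd <- ifelse(n > 1, sqrt(ss / (n - 1)), NA_real_)
  tq <- stats::qt((1 + ci_level) / 2, df = pmax(n - 1, 1))
  half <- ifelse(n > 1, tq * sd / sqrt(n), 0)
  meta <- records[match(levels(f), key), c("group_id", "land_use", "biome")]
  out <- data.frame(meta,
                    mean = m,
                    ci_lower = pmax(0, m - half),
                    ci_upper = pmin(2, m + half),
                    n_experts = n,
                    single_expert = n == 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$group_id, out$land_use, out$biome, na.last = TRUE), , drop = FALSE]
}

#' Resolve biome-level plant scores to ecoregions
#'
#' Ecoregions inherit the plant intactness scores of their biome; mosaic
#' ecoregions (two biomes) get the unweighted mean of the two biomes' mean
#' and confidence bounds. Single-biome ecoregions pass the biome rows through
#' unchanged. `n_experts` for a mosaic is the smaller of the two biomes'
#' expert counts (the more conservative consensus).
#'
#' @param agg Aggregated score table from [aggregate_scores()].
#' @param ecoregion_biomes Data frame with columns `ecoregion_id`, `biome1`
#'   and (NA except for mosaics) `biome2`.
#' @return Data frame keyed by (`ecoregion_id`, `group_id`, `land_use`) with
#'   the same score columns as `agg`; plant rows only.
#' @export
resolve_mosaic_scores <- function(agg, ecoregion_biomes) {
  stopifnot(all(c("ecoregion_id", "biome1") %in% names(ecoregion_biomes)))
  if (!"biome2" %in% names(ecoregion_biomes))
    ecoregion_biomes$biome2 <- NA_character_
  plant <- agg[!is.na(agg$biome), , drop = FALSE]
  combos <- unique(plant[, c("group_id", "land_use")])
  pkey <- paste(plant$group_id, plant$land_use, plant$biome, sep = "\r")

  rows_for <- function(eco, biome) {
    idx <- match(paste(combos$group_id, combos$land_use, biome, sep = "\r"), pkey)
    if (anyNA(idx)) {
      miss <- combos[is.na(idx), , drop = FALSE][1, ]
      stop(sprintf("ecoregion '%s' references biome '%s' with no score for group '%s' in land use '%s'",
                   eco, biome, miss$group_id, miss$land_use))
    }
    plant[idx, , drop = FALSE]
  }

  out <- lapply(seq_len(nrow(ecoregion_biomes)), function(i) {
    e <- ecoregion_biomes$ecoregion_id[i]
    a <- rows_for(e, ecoregion_biomes$biome1[i])
    if (is.na(ecoregion_biomes$biome2[i])) {
      res <- a
    } else {
      b <- rows_for(e, ecoregion_biomes$biome2[i])
      res <- a
      res$mean <- (a$mean + b$mean) / 2
      res$ci_lower <- (a$ci_lower + b$ci_lower) / 2
      res$ci_upper <- (a$ci_upper + b$ci_upper) / 2
      res$n_experts <- pmin(a$n_experts, b$n_experts)
      res$single_expert <- a$single_expert | b$single_expert
    }
    data.frame(ecoregion_id = e, res[, setdiff(names(res), "biome")],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarise expert participation per combination
#'
#' Mean and sample (n-1) standard deviation of the number of experts scoring
#' each (group, land use, biome) combination.
#'
#' @param records Score records from [read_score_table()].
#' @return List with `mean`, `sd` and `n_combinations`.
#' @export
expert_count_summary <- function(records) {
  if (!nrow(records)) stop("no combinations: empty score table")
  counts <- as.integer(table(.combo_key(records)))
  list(mean = mean(counts),
       sd = if (length(counts) > 1) stats::sd(counts) else 0,
       n_combinations = length(counts))
}
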