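#' Genotype-level phenotypic plasticity between two years
#'
#' Plasticity of a genotype is the difference of its mean trait value
#' between the two measurement years (second minus first by sorted year
#' label). Genotypes observed in only one year are excluded; their count is
#' attached as an attribute.
#'
#' @param data long observation data.frame with columns `genotype`, `year`,
#'   `trait`, `value`.
#' @param trait trait name to use.
#' @param absolute if `TRUE`, return |difference| instead of the signed
#'   difference.
#' @return data.frame `genotype`, `plasticity`, with attributes
#'   `year_order` (character(2), the sorted labels used as year1, year2) and
#'   `n_excluded`.
#' @export
genotype_plasticity <- function(data, trait, absolute = FALSE) {
  d <- data[data$trait == trait & !is.na(data$value), ]
  if (!nrow(d)) stop("no observations for trait '", trait, "'")
  yrs <- sort(unique(as.character(d$year)))
  if (length(yrs) != 2L)
    stop("plasticity needs exactly two years; found ", length(yrs))
  m <- tapply(d$value, list(d$genotype, as.character(d$year)), mean)
  complete <- !is.na(m[, yrs[1]]) & !is.na(m[, yrs[2]])
  diff <- m[complete, yrs[2]] - m[complete, yrs[1]]
  if (absolute) diff <- abs(diff)
  out <- data.frame(genotype = rownames(m)[complete], plasticity = diff,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "year_order") <- yrs
  attr(out, "n_excluded") <- sum(!complete)
  out
}

#' Population-level reaction-norm differences from LS means
#'
#' Takes population-by-year least-squares means (from [ls_means()] on a
#' `population:year` style term, or any table with population, year,
#' `lsmean`, `se` columns) and returns the between-year difference per
#' population with error-propagated intervals.
#'
#' @param lsm data.frame containing a population column, a year column,
#'   `lsmean` and `se`. Non-estimable rows (`estimable == FALSE`) are
#'   dropped.
#' @param population,year names of the grouping columns.
#' @return data.frame with `population`, `plasticity` (year2 - year1 by
#'   sorted label), `se`, `lower`, `upper`.
#' @export
population_plasticity <- function(lsm, population = "population",
                                  year = "year") {
  stopifnot(all(c(population, year, "lsmean", "se") %in% names(lsm)))
  if ("estimable" %in% names(lsm)) lsm <- lsm[lsm$estimable, ]
  yrs <- sort(unique(as.character(lsm[[year]])))
  if (length(yrs) != 2L) stop("need exactly two years of LS means")
  a <- lsm[lsm[[year]] == yrs[1], ]
  b <- lsm[lsm[[year]] == yrs[2], ]
  pops <- intersect(a[[population]], b[[population]])
  if (!length(pops)) stop("no population estimable in both years")
  ia <- match(pops, a[[population]]); ib <- match(pops, b[[population]])
  diff <- b$lsmean[ib] - a$lsmean[ia]
  se <- sqrt(a$se[ia]^2 + b$se[ib]^2)
  data.frame(population = pops, plasticity = diff, se = se,
             lower = diff - 1.96 * se, upper = diff + 1.96 * se,
             stringsAsFactors = FALSE)
}

#' Spearman correlation between plasticity and fitness across genotypes
#'
#' @param plasticity data.frame from [genotype_plasticity()].
#' @param fitness data.frame with `genotype` and `fitness` (one row per
#'   genotype, e.g. mean over years).
#' @return List with `rho`, `p`, `n`.
#' @export
fitness_plasticity_correlation <- function(plasticity, fitness) {
  m <- merge(plasticity, fitness, by = "genotype")
  if (nrow(m) < 5L) stop("need at least 5 genotypes with both quantities")
  if (stats::sd(m$plasticity) == 0 || stats::sd(m$fitness) == 0)
    stop("constant input vector: Spearman correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(m$plasticity, m$fitness, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Trait-climate rank correlations in the common garden
#'
#' Correlates individual trait measurements with the garden climate of
#' their measurement year (every observation in a year shares that year's
#' climate value), one Spearman coefficient per trait and climate variable.
#'
#' @param data long observation data.frame (`genotype`, `year`, `trait`,
#'   `value`).
#' @param garden_climate data.frame with a `year` column and one numeric
#'   column per climate variable.
#' @return data.frame `trait`, `climate_var`, `rho`, `p_raw`, `p_holm`;
#'   undefined combinations (constant climate) carry `NA` and a warning is
#'   raised.
#' @export
trait_climate_correlation <- function(data, garden_climate) {
  stopifnot("year" %in% names(garden_climate))
  yrs <- unique(as.character(data$year))
  if (length(yrs) < 2L)
    stop("trait-climate correlation undefined with a single year")
  cvars <- setdiff(names(garden_climate), "year")
  rows <- list()
  for (tr in unique(data$trait)) {
    d <- data[data$trait == tr & !is.na(data$value), ]
    for (cv in cvars) {
      clim <- garden_climate[[cv]][match(as.character(d$year),
                                         as.character(garden_climate$year))]
      if (stats::sd(clim) == 0) {
        warning("climate variable '", cv, "' is constant across years")
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, climate_var = cv, rho = NA_real_, p_raw = NA_real_)
        next
      }
      ct <- suppressWarnings(stats::cor.test(d$value, clim, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, climate_var = cv, rho = unname(ct$estimate),
        p_raw = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_raw)
  out$p_holm <- NA_real_
  if (any(ok)) out$p_holm[ok] <- holm_adjust(out$p_raw[ok])$p_adjusted
  out
}

#' Compare garden and origin climate series
#'
#' Two-sided paired t-test (paired = TRUE) or Wilcoxon rank-sum test
#' (paired = FALSE) of a garden climate series against the corresponding
#' origin series.
#'
#' @param garden,origin numeric vectors (equal length when paired).
#' @param paired logical.
#' @return List with `statistic`, `p`, `method`.
#' @export
climate_comparison <- function(garden, origin, paired = FALSE) {
  garden <- garden[!is.na(garden)]; origin <- origin[!is.na(origin)]
  if (length(garden) < 3L || length(origin) < 3L)
    stop("need at least 3 values per sample")
  if (paired) {
    if (length(garden) != length(origin))
      stop("paired comparison needs equal-length series")
    d <- garden - origin
    if (stats::sd(d) == 0) {
      # degenerate pairs: identical series mean no effect; a constant
      # nonzero shift is unambiguous evidence of one
      return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  p = if (mean(d) == 0) 1 else 0, method = "paired t-test"))
    }
    ht <- stats::t.test(garden, origin, paired = TRUE)
    return(list(statistic = unname(ht$statistic), p = ht$p.value,
                method = "paired t-test"))
  }
  if (length(unique(c(garden, origin))) == 1L) {
    warning("all values tied; no evidence of a location difference")
    return(list(statistic = NA_real_, p = 1, method = "wilcoxon rank-sum"))
  }
  ht <- suppressWarnings(stats::wilcox.test(garden, origin, exact = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = "wilcoxon rank-sum")
}
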