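#' Per-trait specification for the synthetic common-garden generator
#'
#' Defines the variance layers of one trait: a grand mean, a latitudinal
#' cline on population means, and independent Gaussian effects for
#' population, provenance-within-population, year, population-by-year,
#' genotype, and residual (within-clone) variation.
#'
#' @param grand_mean trait grand mean.
#' @param cline_slope change in population mean per degree latitude.
#' @param sd_population SD of population deviations around the cline.
#' @param sd_provenance SD of provenance effects nested in populations.
#' @param sd_year SD of year main effects.
#' @param sd_pop_x_year SD of population-by-year interaction effects.
#' @param sd_genotype SD of genotype (clone) effects.
#' @param sd_residual SD of residual (among-ramet) variation; must be > 0.
#' @param missing_rate probability that a measurement is missing completely
#'   at random, in \[0, 1).
#' @return A list of class `"trait_spec"`.
#' @export
trait_spec <- function(grand_mean = 10, cline_slope = 0,
                       sd_population = 1, sd_provenance = 0,
                       sd_year = 0.5, sd_pop_x_year = 0.5,
                       sd_genotype = 1, sd_residual = 1,
                       missing_rate = 0) {
  sds <- c(sd_population, sd_provenance, sd_year, sd_pop_x_year,
           sd_genotype, sd_residual)
  if (any(sds < 0)) stop("all sd fields must be >= 0")
  if (sd_residual <= 0) stop("sd_residual must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(grand_mean = grand_mean, cline_slope = cline_slope,
                 sd_population = sd_population, sd_provenance = sd_provenance,
                 sd_year = sd_year, sd_pop_x_year = sd_pop_x_year,
                 sd_genotype = sd_genotype, sd_residual = sd_residual,
                 missing_rate = missing_rate),
            class = "trait_spec")
}

#' Default 18-trait panel for the synthetic generator
#'
#' Mimics the structure of a boreal poplar common-garden trial: five
#' phenology traits with strong latitudinal clines and large among-population
#' variance, two biomass traits with moderate clines, and eleven
#' ecophysiology traits with weaker population signal and 30% missingness.
#' Magnitudes are chosen for statistical realism (population differentiation
#' well above drift for phenology, moderate plasticity between years), not to
#' match any particular field dataset.
#'
#' @return Named list of [trait_spec()] objects.
#' @export
default_trait_specs <- function() {
  phen <- c("bud_set", "canopy_duration", "growth_period", "leaf_drop",
            "post_bud_set_period")
  biom <- c("active_growth_rate", "height_diameter_ratio")
  ecop <- c("a_max", "a_max_mass", "c_n_ratio", "delta_leaf", "delta15_n",
            "g_s", "lma_summer", "n_area", "n_mass", "nue", "wue")
  specs <- c(
    lapply(phen, function(nm) trait_spec(
      grand_mean = 200, cline_slope = -3, sd_population = 6, sd_provenance = 1,
      sd_year = 4, sd_pop_x_year = 2, sd_genotype = 3, sd_residual = 5)),
    lapply(biom, function(nm) trait_spec(
      grand_mean = 10, cline_slope = -0.3, sd_population = 1,
      sd_provenance = 0.3, sd_year = 0.8, sd_pop_x_year = 0.4,
      sd_genotype = 0.8, sd_residual = 1)),
    lapply(ecop, function(nm) trait_spec(
      grand_mean = 5, cline_slope = -0.05, sd_population = 0.5,
      sd_provenance = 0.1, sd_year = 0.3, sd_pop_x_year = 0.15,
      sd_genotype = 0.4, sd_residual = 0.8, missing_rate = 0.3))
  )
  names(specs) <- c(phen, biom, ecop)
  specs
}

#' Configuration of a synthetic common-garden study
#'
#' The defaults reproduce the skeleton of a 29-population, three-deme poplar
#' clone trial: roughly 400 genotypes grouped into provenances within
#' populations spanning latitudes 45.6-59.6 degrees N, each genotype
#' replicated by 4-20 ramets and measured in two years.
#'
#' @param n_demes number of genetic demes (populations are assigned to demes
#'   by latitude order).
#' @param n_populations number of populations (>= 2).
#' @param genotypes_per_population single count or range `c(lo, hi)`.
#' @param provenances_per_population provenance groups per population.
#' @param ramets_per_genotype range `c(lo, hi)` of clonal ramets.
#' @param years character vector of year labels (two by default).
#' @param latitude_range range of population latitudes, degrees N.
#' @param trait_specs named list of [trait_spec()] objects.
#' @param fitness_surface named list, one entry per selected trait:
#'   `list(beta_true =, gamma_true =)`; traits absent from the list have no
#'   direct effect on fitness.
#' @param fitness_noise_sd SD of the fitness noise.
#' @param marker_spec list with `n_loci`, `fst_true` in (0,1), and
#'   `ancestral_freq_range`.
#' @param bm_spec list with `rho_true` in (-1,1), `rate_x`, `rate_y`,
#'   `n_tips` for the Brownian trait-climate pair.
#' @param seed integer master seed; identical seeds give identical output.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_demes = 3, n_populations = 29,
                              genotypes_per_population = 14,
                              provenances_per_population = 5,
                              ramets_per_genotype = c(4, 20),
                              years = c("2009", "2010"),
                              latitude_range = c(45.6, 59.6),
                              trait_specs = default_trait_specs(),
                              fitness_surface = list(
                                bud_set = list(beta_true = 0.3, gamma_true = -0.2)),
                              fitness_noise_sd = 0.1,
                              marker_spec = list(n_loci = 500, fst_true = 0.1,
                                                 ancestral_freq_range = c(0.1, 0.9)),
                              bm_spec = list(rho_true = 0.5, rate_x = 1,
                                             rate_y = 1, n_tips = 100),
                              seed = 1L) {
  if (n_populations < 2) stop("need at least 2 populations (Qst is undefined below that)")
  if (n_demes < 1 || n_demes > n_populations) stop("invalid n_demes")
  if (any(genotypes_per_population < 1) || any(ramets_per_genotype < 1))
    stop("counts must be positive")
  if (length(years) < 1) stop("at least one year label required")
  f <- marker_spec$fst_true
  if (!is.null(f) && (f <= 0 || f >= 1)) stop("fst_true must lie in (0, 1)")
  r <- bm_spec$rho_true
  if (!is.null(r) && abs(r) >= 1) stop("rho_true must lie in (-1, 1)")
  if (is.null(names(trait_specs)) || any(names(trait_specs) == ""))
    stop("trait_specs must be a named list")
  bad <- setdiff(names(fitness_surface), names(trait_specs))
  if (length(bad)) stop("fitness_surface refers to unknown traits: ",
                        paste(bad, collapse = ", "))
  structure(list(n_demes = n_demes, n_populations = n_populations,
                 genotypes_per_population = genotypes_per_population,
                 provenances_per_population = provenances_per_population,
                 ramets_per_genotype = ramets_per_genotype,
                 years = years, latitude_range = latitude_range,
                 trait_specs = trait_specs,
                 fitness_surface = fitness_surface,
                 fitness_noise_sd = fitness_noise_sd,
                 marker_spec = marker_spec, bm_spec = bm_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a common-garden trait dataset with known ground truth
#'
#' Draws every variance layer of each trait independently:
#' value = grand_mean + cline * (lat - mean lat) + population + provenance +
#' year + population-by-year + genotype + residual. Measurements are then
#' deleted completely at random at the trait's `missing_rate`. The nesting
#' genotype in provenance in population in deme is strict.
#'
#' @param config a [simulation_config()] object.
#' @return List of class `"garden_sim"` with elements
#'   \describe{
#'     \item{observations}{long data.frame: genotype, ramet, provenance,
#'       population, deme, year, trait, value.}
#'     \item{structure}{one row per genotype: genotype, provenance,
#'       population, deme, latitude, longitude.}
#'     \item{truth}{realized effects, generating variance components, the
#'       true Qst per trait implied by the generating components
#'       (sigma2_between / (sigma2_between + 2 * sigma2_within) with the
#'       within term the provenance-plus-genotype variance), and the
#'       configured selection surface and Brownian correlation.}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  npop <- config$n_populations
  lat <- seq(config$latitude_range[1], config$latitude_range[2], length.out = npop)
  lon <- -138 + 17 * stats::runif(npop)
  pop_ids <- sprintf("P%02d", seq_len(npop))
  deme_labels <- c("oregon", "southern", "northern")[seq_len(min(3, config$n_demes))]
  if (config$n_demes > 3)
    deme_labels <- c(deme_labels, sprintf("deme%d", 4:config$n_demes))
  deme_of_pop <- deme_labels[cut(rank(lat, ties.method = "first"),
                                 breaks = config$n_demes, labels = FALSE)]

  gpp <- config$genotypes_per_population
  n_geno_pop <- if (length(gpp) == 2L)
    sample(gpp[1]:gpp[2], npop, replace = TRUE) else rep(gpp, npop)
  geno_pop <- rep(seq_len(npop), n_geno_pop)
  n_geno <- length(geno_pop)
  geno_ids <- sprintf("G%04d", seq_len(n_geno))
  # assign genotypes to provenances within their population
  prov_of_geno <- unlist(lapply(seq_len(npop), function(i) {
    k <- config$provenances_per_population
    sprintf("%s_V%d", pop_ids[i], sample.int(k, n_geno_pop[i], replace = TRUE))
  }))
  structure_meta <- data.frame(
    genotype = geno_ids,
    provenance = prov_of_geno,
    population = pop_ids[geno_pop],
    deme = deme_of_pop[geno_pop],
    latitude = lat[geno_pop],
    longitude = lon[geno_pop],
    stringsAsFactors = FALSE)

  rr <- config$ramets_per_genotype
  n_ramets <- if (length(rr) == 2L)
    sample(rr[1]:rr[2], n_geno, replace = TRUE) else rep(rr[1], n_geno)
  years <- as.character(config$years)
  n_years <- length(years)

  # one row per genotype x ramet x year, shared across traits
  idx_geno <- rep(seq_len(n_geno), times = n_ramets * n_years)
  ramet <- unlist(lapply(seq_len(n_geno), function(g)
    rep(seq_len(n_ramets[g]), n_years)))
  year <- unlist(lapply(seq_len(n_geno), function(g)
    rep(years, each = n_ramets[g])))
  n_obs <- length(idx_geno)
  idx_pop <- geno_pop[idx_geno]
  idx_year <- match(year, years)

  prov_levels <- sort(unique(prov_of_geno))
  idx_prov <- match(prov_of_geno, prov_levels)[idx_geno]

  obs_list <- vector("list", length(config$trait_specs))
  effects <- list()
  true_qst <- numeric(0)
  lat_c <- lat - mean(lat)
  # population variance of the realized latitudes (n denominator): the cline
  # contribution to among-population variance is part of sigma2_between
  pvar_lat <- mean(lat_c^2)

  for (ti in seq_along(config$trait_specs)) {
    nm <- names(config$trait_specs)[ti]
    sp <- config$trait_specs[[ti]]
    pop_dev <- stats::rnorm(npop, 0, sp$sd_population)
    pop_eff <- sp$cline_slope * lat_c + pop_dev
    prov_eff <- stats::rnorm(length(prov_levels), 0, sp$sd_provenance)
    year_eff <- stats::rnorm(n_years, 0, sp$sd_year)
    pxy_eff <- matrix(stats::rnorm(npop * n_years, 0, sp$sd_pop_x_year),
                      npop, n_years)
    gen_eff <- stats::rnorm(n_geno, 0, sp$sd_genotype)
    value <- sp$grand_mean + pop_eff[idx_pop] + prov_eff[idx_prov] +
      year_eff[idx_year] + pxy_eff[cbind(idx_pop, idx_year)] +
      gen_eff[idx_geno] + stats::rnorm(n_obs, 0, sp$sd_residual)
    keep <- if (sp$missing_rate > 0)
      stats::runif(n_obs) >= sp$missing_rate else rep(TRUE, n_obs)
    obs_list[[ti]] <- data.frame(
      genotype = geno_ids[idx_geno][keep],
      ramet = ramet[keep],
      provenance = prov_of_geno[idx_geno][keep],
      population = pop_ids[idx_pop][keep],
      deme = deme_of_pop[idx_pop][keep],
      year = year[keep],
      trait = nm,
      value = value[keep],
      stringsAsFactors = FALSE)
    effects[[nm]] <- list(population = stats::setNames(pop_eff, pop_ids),
                          provenance = stats::setNames(prov_eff, prov_levels),
                          year = stats::setNames(year_eff, years),
                          pop_x_year = pxy_eff,
                          genotype = stats::setNames(gen_eff, geno_ids))
    s2b <- sp$sd_population^2 + sp$cline_slope^2 * pvar_lat
    s2w <- sp$sd_provenance^2 + sp$sd_genotype^2
    true_qst[nm] <- s2b / (s2b + 2 * s2w)
  }

  truth <- list(
    effects = effects,
    variance_components = lapply(config$trait_specs, function(sp)
      c(population = sp$sd_population^2, provenance = sp$sd_provenance^2,
        year = sp$sd_year^2, pop_x_year = sp$sd_pop_x_year^2,
        genotype = sp$sd_genotype^2, residual = sp$sd_residual^2)),
    true_qst = true_qst,
    fitness_surface = config$fitness_surface,
    fitness_noise_sd = config$fitness_noise_sd,
    fst_true = config$marker_spec$fst_true,
    rho_true = config$bm_spec$rho_true,
    seed = config$seed)

  structure(list(observations = do.call(rbind, obs_list),
                 structure = structure_meta,
                 truth = truth, config = config),
            class = "garden_sim")
}

#' @export
print.garden_sim <- function(x, ...) {
  cat("Synthetic common-garden dataset\n")
  cat(sprintf("  %d observations, %d genotypes, %d populations, %d deme(s)\n",
              nrow(x$observations), nrow(x$structure),
              length(unique(x$structure$population)),
              length(unique(x$structure$deme))))
  cat(sprintf("  traits: %s\n",
              paste(utils::head(unique(x$observations$trait), 6), collapse = ", ")))
  invisible(x)
}

#' Construct fitness from a known selection surface
#'
#' Inverts a phenotypic selection analysis: given standardized genotype mean
#' traits z, fitness is built as
#' W = w0 + sum(beta_k z_k) + sum(gamma_k / 2 * z_k^2) + noise,
#' with baseline w0 = 1 - sum(gamma_k) / 2 so that mean fitness is close to
#' 1 and regressions of relative fitness on z recover beta and gamma
#' exactly. A strongly concave surface is negative in the deep trait tail;
#' by default those rare values are kept (the fraction is recorded), because
#' flooring them would attenuate the realized quadratic surface and break
#' the generator's covariance contract. Set `floor` to clip instead when a
#' strictly positive fitness is required.
#'
#' @param traits data.frame with columns `genotype`, `year`, and one column
#'   per trait, standardized within year.
#' @param surface named list per trait: `list(beta_true =, gamma_true =)`.
#'   `gamma_true` is on the doubled (selection-differential) scale; the
#'   quadratic coefficient used is `gamma_true / 2`.
#' @param noise_sd SD of Gaussian fitness noise.
#' @param floor `NULL` (default) for no clipping, or a fraction of mean
#'   fitness (e.g. 0.01) below which values are clipped.
#' @param seed optional integer seed.
#' @return data.frame `genotype`, `year`, `fitness`, with attributes
#'   `clipped_fraction`, `negative_fraction` and `w0`.
#' @export
simulate_fitness <- function(traits, surface, noise_sd = 0.1, floor = NULL,
                             seed = NULL) {
  stopifnot(is.data.frame(traits), all(c("genotype", "year") %in% names(traits)))
  bad <- setdiff(names(surface), names(traits))
  if (length(bad)) stop("fitness surface references absent trait(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  gam_sum <- sum(vapply(surface, function(s) s$gamma_true, 0))
  w0 <- 1 - gam_sum / 2
  W <- rep(w0, nrow(traits))
  for (nm in names(surface)) {
    z <- traits[[nm]]
    W <- W + surface[[nm]]$beta_true * z + surface[[nm]]$gamma_true / 2 * z^2
  }
  W <- W + stats::rnorm(length(W), 0, noise_sd)
  negative <- mean(W < 0)
  clipped <- 0
  if (!is.null(floor)) {
    floor_w <- floor * mean(W)
    cl <- W < floor_w
    W[cl] <- floor_w
    clipped <- mean(cl)
  }
  out <- data.frame(genotype = traits$genotype, year = traits$year,
                    fitness = W, stringsAsFactors = FALSE)
  attr(out, "clipped_fraction") <- clipped
  attr(out, "negative_fraction") <- negative
  attr(out, "w0") <- w0
  out
}

#' Simulate diploid markers under the Balding-Nichols model
#'
#' Ancestral allele frequencies are uniform on `ancestral_freq_range`;
#' population frequencies follow Beta(p (1 - F) / F, (1 - p)(1 - F) / F)
#' with F the target Fst; individual counts are Binomial(2, population
#' frequency).
#'
#' @param config a [simulation_config()] (its `marker_spec` is used), or a
#'   bare list with `n_loci`, `fst_true`, `ancestral_freq_range`.
#' @param populations optional character vector of population labels, one
#'   per genotype; defaults to the configured design.
#' @param seed optional integer seed (defaults to the config seed).
#' @return Integer matrix (genotypes x loci) with entries in {0, 1, 2} and a
#'   `"population"` attribute.
#' @export
simulate_markers <- function(config, populations = NULL, seed = NULL) {
  spec <- if (inherits(config, "sim_config")) config$marker_spec else config
  if (is.null(spec$n_loci) || spec$n_loci < 1) stop("n_loci must be >= 1")
  F <- spec$fst_true
  if (F <= 0 || F >= 1) stop("fst_true must lie in (0, 1)")
  if (is.null(populations)) {
    if (!inherits(config, "sim_config"))
      stop("populations must be given when config is a bare marker spec")
    gpp <- config$genotypes_per_population
    gpp <- if (length(gpp) == 2L) round(mean(gpp)) else gpp
    populations <- rep(sprintf("P%02d", seq_len(config$n_populations)), each = gpp)
  }
  if (!is.null(seed)) set.seed(seed)
  else if (inherits(config, "sim_config")) set.seed(config$seed + 1L)
  n_ind <- length(populations)
  pops <- unique(populations)
  L <- spec$n_loci
  rng <- spec$ancestral_freq_range %||% c(0.1, 0.9)
  p_anc <- stats::runif(L, rng[1], rng[2])
  shape_scale <- (1 - F) / F
  G <- matrix(0L, n_ind, L,
              dimnames = list(sprintf("G%04d", seq_len(n_ind)),
                              sprintf("L%04d", seq_len(L))))
  for (k in seq_along(pops)) {
    rows <- which(populations == pops[k])
    pf <- stats::rbeta(L, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    G[rows, ] <- matrix(stats::rbinom(length(rows) * L, 2L, rep(pf, each = length(rows))),
                        nrow = length(rows))
  }
  attr(G, "population") <- populations
  attr(G, "fst_true") <- F
  G
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a correlated pair of Brownian traits on a phylogeny
#'
#' Tip values are drawn from the matrix normal with row covariance C (the
#' shared-branch-length matrix of the tree) and column covariance R built
#' from the rates and correlation rho, i.e. vec(Y) ~ N(mu, R kron C).
#'
#' @param tree an `ape::phylo` tree with positive branch lengths.
#' @param rho Brownian cross-correlation, |rho| < 1.
#' @param rates length-2 vector of Brownian rates (variances per unit branch
#'   length) for the two traits.
#' @param mu length-2 vector of root means.
#' @param seed optional integer seed.
#' @return data.frame with columns `tip`, `x`, `y`.
#' @export
simulate_bm_pair <- function(tree, rho, rates = c(1, 1), mu = c(0, 0),
                             seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (any(rates <= 0)) stop("rates must be positive")
  if (any(tree$edge.length < 0)) stop("tree must have non-negative branch lengths")
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  n <- nrow(C)
  Lc <- t(chol(C + diag(1e-12 * mean(diag(C)), n)))
  R <- diag(sqrt(rates)) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sqrt(rates))
  Z <- matrix(stats::rnorm(2 * n), n, 2)
  Y <- Lc %*% Z %*% chol(R)
  data.frame(tip = rownames(C), x = mu[1] + Y[, 1], y = mu[2] + Y[, 2],
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to tidy text files
#'
#' Emits `observations.csv`, `structure.csv`, optionally `markers.csv`, a
#' `ground_truth.json`, and a Newick tree when supplied.
#'
#' @param sim a `"garden_sim"` object.
#' @param dir output directory (created if needed).
#' @param markers optional marker matrix from [simulate_markers()].
#' @param tree optional `phylo` tree.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(sim, dir, markers = NULL, tree = NULL) {
  stopifnot(inherits(sim, "garden_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "observations.csv")
  utils::write.csv(sim$observations, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "structure.csv")
  utils::write.csv(sim$structure, f, row.names = FALSE)
  files <- c(files, f)
  truth <- sim$truth
  truth$effects <- NULL  # realized effect vectors are large; keep scalars
  f <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (!is.null(markers)) {
    f <- file.path(dir, "markers.csv")
    utils::write.csv(cbind(data.frame(genotype = rownames(markers),
                                      population = attr(markers, "population")),
                           as.data.frame(markers)), f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(tree)) {
    f <- file.path(dir, "tree.nwk")
    ape::write.tree(tree, f)
    files <- c(files, f)
  }
  invisible(files)
}
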