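#' Genotype-by-year trait means in wide form
#'
#' Collapses ramet-level observations to genotype means per year and trait;
#' the usual input grain for the selection analysis.
#'
#' @param observations long data.frame (`genotype`, `year`, `trait`,
#'   `value`).
#' @param traits traits to include (default: all).
#' @param standardized if `TRUE`, z-score each trait within year.
#' @return data.frame `genotype`, `year`, one column per trait.
#' @export
genotype_year_means <- function(observations, traits = NULL,
                                standardized = FALSE) {
  if (is.null(traits)) traits <- unique(observations$trait)
  d <- observations[observations$trait %in% traits & !is.na(observations$value), ]
  key <- paste(d$genotype, d$year, sep = "\r")
  base <- unique(data.frame(genotype = d$genotype, year = d$year, key = key,
                            stringsAsFactors = FALSE))
  out <- base[order(base$genotype, base$year), c("genotype", "year")]
  rownames(out) <- NULL
  okey <- paste(out$genotype, out$year, sep = "\r")
  for (tr in traits) {
    dt <- d[d$trait == tr, ]
    m <- tapply(dt$value, paste(dt$genotype, dt$year, sep = "\r"), mean)
    v <- unname(m[okey])
    if (standardized) {
      ok <- !is.na(v)
      v[ok] <- standardize(v[ok], out$year[ok])
    }
    out[[tr]] <- v
  }
  out
}

#' Run the full common-garden analysis pipeline on synthetic data
#'
#' Stages run in dependency order: simulate, variance partitioning (REML
#' mixed models per trait), plasticity, Qst-Fst, selection, coevolution.
#' Every stage draws its seed from the master seed by a fixed offset, so
#' identical configurations give byte-identical outputs. When `outdir` is
#' given, each enabled stage writes one tidy CSV, plus a ground-truth JSON
#' and a provenance JSON (seed, configuration hash, stage settings).
#'
#' @param config a [simulation_config()].
#' @param outdir optional output directory.
#' @param stages character subset of
#'   c("variance", "plasticity", "qstfst", "selection", "coevolution").
#' @param alpha significance level used in classifications and the Holm
#'   flags.
#' @param n_perm permutations for the selection tests.
#' @param qst_n_iter,qst_burnin Gibbs settings for the Qst posteriors.
#' @param ss_stones,ss_iters stepping-stone schedule for the coevolution
#'   Bayes factors.
#' @return Invisibly, a named list of result tables (plus `truth`).
#' @export
run_pipeline <- function(config = simulation_config(), outdir = NULL,
                         stages = c("variance", "plasticity", "qstfst",
                                    "selection", "coevolution"),
                         alpha = 0.05, n_perm = 1000,
                         qst_n_iter = 10000, qst_burnin = 0.10,
                         ss_stones = 50, ss_iters = 500) {
  stages <- match.arg(stages, several.ok = TRUE)
  t_all <- list()
  sim <- simulate_dataset(config)
  obs <- sim$observations
  traits <- names(config$trait_specs)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if ("variance" %in% stages) {
    rows <- lapply(traits, function(tr) {
      d <- obs[obs$trait == tr, ]
      full <- fit_reml(value ~ year + population + year:population, d,
                       random = ~ genotype)
      red <- fit_reml(value ~ year + population + year:population, d)
      an <- anova(full)
      lrt <- lrt_random(full, red)
      data.frame(trait = tr,
                 term = c(an$term, "genetics"),
                 statistic = c(an$F, lrt$chisq),
                 df_num = c(an$df_num, 1),
                 df_den = c(round(an$df_den, 1), NA),
                 p = c(an$p, lrt$p),
                 sigma2_genotype = full$sigma2["random"],
                 sigma2_residual = full$sigma2["residual"],
                 r_squared = full$r_squared, aic = full$aic,
                 reml_criterion = -2 * full$logLik,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_holm <- stats::ave(tab$p, tab$term,
                             FUN = function(p) holm_adjust(p)$p_adjusted)
    t_all$variance_components <- tab
  }

  if ("plasticity" %in% stages) {
    rows <- lapply(traits, function(tr) {
      gp <- genotype_plasticity(obs, tr)
      data.frame(trait = tr, genotype = gp$genotype,
                 plasticity = gp$plasticity, stringsAsFactors = FALSE)
    })
    t_all$plasticity <- do.call(rbind, rows)
  }

  if ("qstfst" %in% stages) {
    markers <- simulate_markers(config, seed = stage_seed(config$seed, 101))
    fst <- weir_cockerham_fst(markers, attr(markers, "population"),
                              seed = stage_seed(config$seed, 102))
    rows <- lapply(seq_along(traits), function(i) {
      tr <- traits[i]
      ch <- mcmc_variance_components(obs, tr, n_iter = qst_n_iter,
                                     burnin = qst_burnin,
                                     seed = stage_seed(config$seed, 200 + i))
      q <- compute_qst(ch, trait = tr)
      data.frame(trait = tr, qst = q$qst, ci_low = q$ci[1], ci_high = q$ci[2],
                 fst = fst$theta, fst_ci_low = fst$ci[1],
                 fst_ci_high = fst$ci[2],
                 classification = classify_divergence(q, fst),
                 true_qst = sim$truth$true_qst[tr],
                 stringsAsFactors = FALSE)
    })
    t_all$qst_fst <- do.call(rbind, rows)
  }

  if ("selection" %in% stages) {
    zc <- genotype_year_means(obs, traits, standardized = TRUE)
    surf_traits <- names(config$fitness_surface)
    fz <- zc[stats::complete.cases(zc[, surf_traits, drop = FALSE]), ]
    fit_tab <- simulate_fitness(fz[, c("genotype", "year", surf_traits)],
                                config$fitness_surface,
                                noise_sd = config$fitness_noise_sd,
                                seed = stage_seed(config$seed, 300))
    note("fitness negative fraction: %.4f", attr(fit_tab, "negative_fraction"))
    key <- paste(fit_tab$genotype, fit_tab$year)
    w_all <- suppressWarnings(relative_fitness(fit_tab$fitness, fit_tab$year))
    sel_rows <- list(); het_rows <- list()
    for (i in seq_along(traits)) {
      tr <- traits[i]
      z_all <- zc[[tr]][match(key, paste(zc$genotype, zc$year))]
      for (yr in sort(unique(fit_tab$year))) {
        iy <- fit_tab$year == yr & !is.na(z_all)
        if (sum(iy) < 6) next
        sd_seed <- stage_seed(config$seed, 310 + 7L * i)
        lin <- linear_differential(w_all[iy], z_all[iy], n_perm = n_perm,
                                   seed = sd_seed)
        quad <- quadratic_differential(w_all[iy], z_all[iy], n_perm = n_perm,
                                       seed = sd_seed + 1L)
        cls <- classify_selection(lin$estimate, lin$p, quad$estimate, quad$p,
                                  quad$z_star, range(z_all[iy]), alpha)
        sel_rows[[length(sel_rows) + 1L]] <- data.frame(
          trait = tr, year = yr, beta = lin$estimate, p_beta = lin$p,
          gamma = quad$estimate, p_gamma = quad$p,
          stars_beta = as.character(p_stars(lin$p)),
          stars_gamma = as.character(p_stars(quad$p)),
          z_star = quad$z_star, classification = cls,
          stringsAsFactors = FALSE)
      }
      okh <- !is.na(z_all)
      if (length(unique(fit_tab$year[okh])) == 2L) {
        het <- heterogeneity_test(w_all[okh], z_all[okh], fit_tab$year[okh])
        het_rows[[length(het_rows) + 1L]] <- data.frame(
          trait = tr, interaction = het$estimate, F = het$F,
          df_num = het$df_num, df_den = het$df_den, p = het$p,
          stringsAsFactors = FALSE)
      }
    }
    t_all$selection <- do.call(rbind, sel_rows)
    t_all$heterogeneity <- do.call(rbind, het_rows)
    if (!is.null(t_all$heterogeneity))
      t_all$heterogeneity$p_holm <- holm_adjust(t_all$heterogeneity$p)$p_adjusted
  }

  if ("coevolution" %in% stages) {
    markers <- simulate_markers(config, seed = stage_seed(config$seed, 101))
    pops <- attr(markers, "population")
    fr <- rowsum(markers, pops)
    cnt <- as.vector(table(pops)[rownames(fr)])
    freq <- fr / (2 * cnt)
    D <- as.matrix(stats::dist(freq))
    tree <- build_nj_tree(D)
    bm <- config$bm_spec
    pair <- simulate_bm_pair(tree, bm$rho_true,
                             rates = c(bm$rate_x, bm$rate_y),
                             seed = stage_seed(config$seed, 400))
    x <- stats::setNames(pair$x, pair$tip)
    y <- stats::setNames(pair$y, pair$tip)
    post <- mcmc_bm(tree, x, y, dependent = TRUE, n_iter = 4000,
                    burnin = 1000, seed = stage_seed(config$seed, 401))
    dep <- stepping_stone_logml(tree, x, y, dependent = TRUE,
                                n_stones = ss_stones,
                                iters_per_stone = ss_iters,
                                seed = stage_seed(config$seed, 402))
    ind <- stepping_stone_logml(tree, x, y, dependent = FALSE,
                                n_stones = ss_stones,
                                iters_per_stone = ss_iters,
                                seed = stage_seed(config$seed, 403))
    bf <- log_bayes_factor(dep, ind)
    t_all$coevolution <- data.frame(
      trait = "bm_trait", climate_var = "bm_climate",
      rho_posterior_mean = post$rho_mean,
      rho_ci_low = post$rho_ci[1], rho_ci_high = post$rho_ci[2],
      logml_dependent = dep$logml, logml_independent = ind$logml,
      logBF = bf$logBF, support = bf$support,
      passes_multiplicity_threshold = bf$passes_multiplicity_threshold,
      rho_true = bm$rho_true, stringsAsFactors = FALSE)
  }

  t_all$truth <- sim$truth
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(t_all), "truth"))
      utils::write.csv(t_all[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    truth_out <- sim$truth
    truth_out$effects <- NULL
    jsonlite::write_json(truth_out, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    prov <- list(seed = config$seed, config_hash = config_hash(config),
                 stages = stages, alpha = alpha, n_perm = n_perm,
                 qst_n_iter = qst_n_iter, ss_stones = ss_stones,
                 ss_iters = ss_iters,
                 tables = setdiff(names(t_all), "truth"),
                 log = log_lines,
                 package_version = as.character(utils::packageVersion("gardenQG")))
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(t_all)
}
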