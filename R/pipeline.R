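# End-to-end pipeline orchestration.

default_pipeline_config <- function() {
  list(
    seed = 1,
    input = list(genepop = NULL, grouping = NULL),   # NULL -> fixture
    fixture = list(),
    stages = list(outliers = TRUE, diversity = TRUE, amova = TRUE,
                  structure = TRUE, dapc = TRUE, abc = TRUE,
                  envassoc = TRUE),
    outliers = list(iterations = 20000, burn_in = 10000, thinning = 20,
                    prior_odds = 10),
    amova = list(n_perm = 499),
    structure = list(k_range = 1:4, n_runs = 3, burn_in = 2000,
                     iterations = 8000),
    dapc = list(n_pcs = 2, groups = "species"),
    abc = list(models = c("CI", "AM", "SC", "CM"), n_sims = 1000,
               n_keep = 400, n_components = 5, n_loci = NULL),
    envassoc = list(n_perm = 999))
}

# fixed seed-splitting rule: stage k of global seed s gets s * 100 + k
stage_seed <- function(seed, k) (seed %% 20000000L) * 100L + k

# order-insensitive structural hash of a result object (text rolling
# hash of its JSON serialization at 8 significant digits)
light_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 8, force = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}

check_config_keys <- function(cfg, defaults, path = "config") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in intersect(names(cfg), names(defaults)))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(cfg[[nm]]) && nm != "fixture")
      check_config_keys(cfg[[nm]], defaults[[nm]], paste0(path, "$", nm))
  invisible(TRUE)
}

#' Run the full inference pipeline
#'
#' Orders the stages as the study design does: outlier scan, locus
#' split, diversity and AMOVA on the total / neutral / positive-outlier
#' sets, clustering (admixture MCMC over a K range plus Evanno
#' delta-K) and DAPC, ABC model choice on the neutral loci, and
#' environment association. Each stage draws its seed from the global
#' seed by a fixed splitting rule, so stages are individually
#' reproducible; effective parameters, seeds and result hashes go into
#' the manifest.
#'
#' @param config nested list; see `ssrdiverge:::default_pipeline_config()`
#'   for the keys. Unknown keys are rejected.
#' @return list of per-stage results plus `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- default_pipeline_config()
  check_config_keys(config, defaults)
  cfg <- utils::modifyList(defaults, config)
  res <- list()
  manifest <- list(package = "ssrdiverge",
                   version = as.character(utils::packageVersion("ssrdiverge")),
                   seed = cfg$seed, stages = list())
  note <- function(stage, params, value) {
    manifest$stages[[stage]] <<- list(seed = stage_seed(cfg$seed,
                                                        length(manifest$stages) + 1L),
                                      params = params,
                                      hash = light_hash(value))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(jsonlite::toJSON(list(stage = stage,
                                 error = conditionMessage(e)),
                            auto_unbox = TRUE), call. = FALSE)
    })
  }

  # input
  if (!is.null(cfg$input$genepop)) {
    ds <- run_stage("input", read_genepop(cfg$input$genepop,
                                          grouping = cfg$input$grouping))
  } else {
    ds <- run_stage("input", make_genotype_fixture(cfg$fixture,
                                                   seed = stage_seed(cfg$seed, 1L)))
  }
  res$dataset <- ds

  # outlier scan and locus split
  sets <- list(total = ds)
  if (isTRUE(cfg$stages$outliers)) {
    res$outliers <- run_stage("outliers", {
      chain <- fit_outlier_scan(
        ds, iterations = cfg$outliers$iterations,
        burn_in = cfg$outliers$burn_in, thinning = cfg$outliers$thinning,
        prior_odds = cfg$outliers$prior_odds,
        seed = stage_seed(cfg$seed, 2L))
      classify_outliers(chain)
    })
    sets <- run_stage("outliers", split_loci(ds, res$outliers))
    note("outliers", cfg$outliers, res$outliers)
  }
  neutral <- sets$neutral %||% ds

  if (isTRUE(cfg$stages$diversity)) {
    res$diversity <- run_stage("diversity", diversity_table(ds))
    note("diversity", list(), res$diversity)
  }
  if (isTRUE(cfg$stages$amova)) {
    res$amova <- run_stage("amova", lapply(sets, function(s) {
      if (length(s$loci) == 0) return(NULL)
      tryCatch(amova(s, n_perm = cfg$amova$n_perm,
                     seed = stage_seed(cfg$seed, 3L)),
               error = function(e) NULL)
    }))
    note("amova", cfg$amova, lapply(res$amova, function(a)
      if (is.null(a)) NULL else a$table))
  }
  if (isTRUE(cfg$stages$structure)) {
    res$structure <- run_stage("structure", {
      runs <- list()
      i <- 0L
      for (k in cfg$structure$k_range) for (r in seq_len(cfg$structure$n_runs)) {
        i <- i + 1L
        runs[[i]] <- admixture_mcmc(
          neutral, k, burn_in = cfg$structure$burn_in,
          iterations = cfg$structure$iterations,
          seed = stage_seed(cfg$seed, 10L + i))
      }
      list(runs = runs, deltak = evanno_deltak(runs))
    })
    note("structure", cfg$structure, res$structure$deltak)
  }
  if (isTRUE(cfg$stages$dapc)) {
    res$dapc <- run_stage("dapc", dapc_fit(neutral,
                                           groups = cfg$dapc$groups,
                                           n_pcs = cfg$dapc$n_pcs))
    note("dapc", cfg$dapc, res$dapc$membership)
  }
  if (isTRUE(cfg$stages$abc)) {
    res$abc <- run_stage("abc", {
      obs <- suppressWarnings(summary_stats(neutral))
      sizes <- pipeline_sizes(neutral)
      ref <- build_reference_table(
        cfg$abc$models, default_priors(), sizes,
        n_loci = cfg$abc$n_loci %||% length(neutral$loci),
        n_sims = cfg$abc$n_sims, seed = stage_seed(cfg$seed, 4L))
      abc_model_choice(ref, obs, n_components = cfg$abc$n_components,
                       n_keep = cfg$abc$n_keep)
    })
    note("abc", cfg$abc, res$abc$table)
  }
  if (isTRUE(cfg$stages$envassoc)) {
    res$envassoc <- run_stage("envassoc", {
      envfix <- make_env_fixture(seed = stage_seed(cfg$seed, 5L))
      indenv <- join_env(ds, envfix$populations)
      gpc <- genetic_pcs(ds, n_pcs = 2)
      # five sampling sites support four constraints at most;
      # bio13 is the variable the design drops
      vars <- setdiff(default_env_config()$variables, "bio13")
      pcc <- grep("^PC", names(gpc), value = TRUE)
      ord <- dbrda_env(gpc[, pcc], indenv, predictors = vars,
                       n_perm = cfg$envassoc$n_perm,
                       seed = stage_seed(cfg$seed, 6L))
      pca <- pca_env(envfix$occurrences, variables = vars)
      kw <- kw_species_test(pca$scores, "species",
                            axes = c("PC1", "PC2", "PC3"))
      logit <- logistic_species(pca$scores, "species",
                                predictors = c("PC1", "PC2", "PC3"))
      list(dbrda = ord, env_pca = pca, kw = kw, logistic = logit)
    })
    note("envassoc", cfg$envassoc,
         list(res$envassoc$kw, res$envassoc$dbrda$tests))
  }
  res$manifest <- manifest
  res
}

# two-deme sample-size layout of an observed dataset (populations
# grouped by species, in input order)
pipeline_sizes <- function(ds) {
  map <- unique(ds$individuals[, c("population", "species")])
  counts <- table(ds$individuals$population)
  sps <- unique(map$species)
  if (length(sps) != 2) stop("need exactly 2 species for the two-deme map",
                             call. = FALSE)
  out <- lapply(sps, function(s) {
    pops <- map$population[map$species == s]
    setNames(as.integer(counts[pops]), pops)
  })
  names(out) <- sps
  out
}
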