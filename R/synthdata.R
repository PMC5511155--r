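# Synthetic-data generators with serialized ground truth.

#' Default genotype-fixture configuration
#'
#' Study-shaped defaults: AM scenario (split 1.1e5 generations ago,
#' ancestral gene flow 0.1 in both directions during the first half of
#' divergence), diploid effective sizes 300, SMM mutation at 5e-4,
#' inbreeding duplication 0.6, five populations (10/19/22/15/15) in
#' two species, 15 neutral + 3 positive + 1 balancing loci, and the
#' He / F acceptance bands of the sampled populations.
#'
#' @return named list understood by [make_genotype_fixture()].
#' @export
default_fixture_config <- function() {
  list(
    model = "AM",
    n1 = 300, n2 = 300, n_anc = 300,
    t2 = 1.1e5, t1 = 5.5e4, m12 = 0.1, m21 = 0.1,
    mu = 5e-4, p_geom = 0, f_is = 0.6,
    sample_sizes = list(
      playfairii = c(Wutai = 10, Wulu_pla = 19),
      tashiroi = c(Wulu_tas = 22, Lanyu = 15, Taroko = 15)),
    n_neutral = 15, n_positive = 3, n_balancing = 1,
    he_band = c(0.23, 0.37), f_band = c(0.39, 0.73),
    check_bands = TRUE, max_retries = 5)
}

# species-differentiated, fully homozygous outlier loci: every
# individual carries two copies of its group's allele.
plant_positive_locus <- function(ind, pattern) {
  grp <- switch(pattern,
                species = ind$species,
                wulu_split = ifelse(ind$species == ind$species[1],
                                    ind$population, ind$species))
  lv <- unique(grp)
  a <- 100L + 10L * (match(grp, lv) - 1L)
  cbind(a, a)
}

# balancing-selection-like locus: identical intermediate frequencies in
# every population (HWE draws), deflating FST below the neutral floor.
plant_balancing_locus <- function(n) {
  a1 <- ifelse(runif(n) < 0.5, 100L, 110L)
  a2 <- ifelse(runif(n) < 0.5, 100L, 110L)
  cbind(a1, a2)
}

#' Generate a study-shaped genotype fixture with planted outliers
#'
#' Simulates neutral loci under a divergence scenario via the
#' structured coalescent, maps the two demes onto the five labelled
#' populations of the sampling design, then appends planted outlier
#' loci: positive outliers as fully homozygous, group-diagnostic loci
#' (frequency-shift construction, not a selection simulation) and a
#' balancing-type locus with identical intermediate frequencies
#' everywhere. Realized neutral-locus diversity is checked against the
#' configured bands (mean expected heterozygosity and mean fixation
#' index across populations); the scenario is re-simulated up to
#' `max_retries` times and an error is raised if the band stays
#' unreachable.
#'
#' @param config list overriding [default_fixture_config()] entries.
#' @param seed RNG seed (the fixture is reproducible from
#'   config + seed).
#' @return [microsat_data()] object with a `truth` attribute
#'   (scenario, locus classes, seed, config).
#' @export
make_genotype_fixture <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_fixture_config(), config)
  spec <- scenario_spec(cfg$model, n1 = cfg$n1, n2 = cfg$n2,
                        n_anc = cfg$n_anc, t2 = cfg$t2, t1 = cfg$t1,
                        m12 = cfg$m12, m21 = cfg$m21, mu = cfg$mu,
                        p_geom = cfg$p_geom, f_is = cfg$f_is,
                        sample_sizes = cfg$sample_sizes)
  set.seed(seed)
  realized <- c(he = NA_real_, f = NA_real_)
  ds <- NULL
  for (try in seq_len(max(1, cfg$max_retries))) {
    cand <- simulate_dataset(spec, n_loci = cfg$n_neutral)
    div <- diversity_table(cand)
    realized <- c(he = mean(div$he), f = mean(div$f, na.rm = TRUE))
    ok <- !cfg$check_bands ||
      (is.finite(realized["he"]) && is.finite(realized["f"]) &&
       realized["he"] >= cfg$he_band[1] && realized["he"] <= cfg$he_band[2] &&
       realized["f"] >= cfg$f_band[1] && realized["f"] <= cfg$f_band[2])
    if (ok) { ds <- cand; break }
  }
  if (is.null(ds))
    stop(sprintf(paste0("diversity band unreachable after %d tries ",
                        "(realized He = %.3f, F = %.3f)"),
                 cfg$max_retries, realized["he"], realized["f"]),
         call. = FALSE)
  ind <- ds$individuals
  neutral_names <- sprintf("ssr%02d", seq_len(cfg$n_neutral))
  pos_names <- c("aus9-2", "aus9-3", "aus9-5")[seq_len(cfg$n_positive)]
  bal_names <- if (cfg$n_balancing > 0)
    sprintf("aus9-n%d", seq_len(cfg$n_balancing)) else character(0)
  extra <- c(pos_names, bal_names)
  n <- nrow(ind)
  L <- cfg$n_neutral + length(extra)
  alleles <- array(NA_integer_, c(n, L, 2))
  alleles[, seq_len(cfg$n_neutral), ] <- ds$alleles
  li <- cfg$n_neutral
  pos_patterns <- rep(c("species", "wulu_split"),
                      length.out = cfg$n_positive)
  for (i in seq_len(cfg$n_positive)) {
    li <- li + 1L
    alleles[, li, ] <- plant_positive_locus(ind, pos_patterns[i])
  }
  for (i in seq_len(cfg$n_balancing)) {
    li <- li + 1L
    alleles[, li, ] <- plant_balancing_locus(n)
  }
  out <- microsat_data(alleles, ind, c(neutral_names, extra))
  attr(out, "truth") <- list(
    scenario = spec, seed = seed, config = cfg,
    neutral_loci = neutral_names, positive_loci = pos_names,
    balancing_loci = bal_names,
    realized = as.list(realized))
  out
}

#' Ground truth of a synthetic fixture
#'
#' @param x fixture produced by a `make_*_fixture()` generator.
#' @param path optional file; if given, the truth list is serialized
#'   as JSON there.
#' @return the truth list, invisibly when writing.
#' @export
ground_truth <- function(x, path = NULL) {
  tr <- attr(x, "truth")
  if (is.null(tr)) stop("no ground truth attached", call. = FALSE)
  if (!is.null(path)) {
    jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    return(invisible(tr))
  }
  tr
}

#' Default environmental-fixture configuration
#'
#' @return named list understood by [make_env_fixture()].
#' @export
default_env_config <- function() {
  list(
    variables = c("alt", "AET", "bio3", "bio13", "bio14"),
    correlation = 0.25,        # scalar -> compound-symmetric target
    shift = 2.2,               # species mean shift, sd units
    direction = NULL,          # default: equal loadings
    n_occurrences = c(playfairii = 23, tashiroi = 16),
    populations = tibble::tibble(
      population = c("Wutai", "Wulu_pla", "Wulu_tas", "Lanyu", "Taroko"),
      species = c("playfairii", "playfairii", "tashiroi", "tashiroi",
                  "tashiroi")),
    occurrence_sd = 0.6,       # within-species scatter around the mean
    add_duplicate = FALSE)     # collinear decoy to exercise vif_prune
}

#' Generate an environmental fixture with a planted species shift
#'
#' Multivariate Gaussian environmental variables with a configurable
#' correlation target; the two species differ only by a mean shift
#' along one declared linear combination of the variables, so that no
#' single variable separates the species but the leading principal
#' component does. Produces occurrence-level and population-level
#' tables.
#'
#' @param config list overriding [default_env_config()].
#' @param seed RNG seed.
#' @return list: `occurrences` (tibble, one row per record),
#'   `populations` (tibble, one row per population), `truth`
#'   (direction, shift, correlation).
#' @export
make_env_fixture <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_env_config(), config)
  vars <- cfg$variables
  p <- length(vars)
  if (p < 5) stop("configure >= 5 variables", call. = FALSE)
  R <- cfg$correlation
  if (is.matrix(R)) {
    if (nrow(R) != p) stop("correlation matrix size mismatch", call. = FALSE)
  } else {
    R <- matrix(R, p, p); diag(R) <- 1
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation target not positive definite",
                         call. = FALSE)
  w <- cfg$direction %||% rep(1, p)
  w <- w / sqrt(sum(w^2))
  set.seed(seed)
  species <- rep(names(cfg$n_occurrences), cfg$n_occurrences)
  n <- length(species)
  mu_shift <- outer(ifelse(species == species[1], -0.5, 0.5) * cfg$shift, w)
  X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R) + mu_shift
  colnames(X) <- vars
  occ <- dplyr::bind_cols(tibble::tibble(species = species),
                          tibble::as_tibble(as.data.frame(X)))
  # population-level values: species mean + within-species scatter
  pops <- cfg$populations
  pshift <- outer(ifelse(pops$species == species[1], -0.5, 0.5) * cfg$shift,
                  w)
  P <- MASS::mvrnorm(nrow(pops), mu = rep(0, p), Sigma = R) *
    cfg$occurrence_sd + pshift
  colnames(P) <- vars
  poptab <- dplyr::bind_cols(pops, tibble::as_tibble(as.data.frame(P)))
  if (isTRUE(cfg$add_duplicate)) {
    occ$alt_copy <- occ$alt
    poptab$alt_copy <- poptab$alt
  }
  truth <- list(direction = setNames(as.list(w), vars), shift = cfg$shift,
                correlation = R, seed = seed)
  out <- list(occurrences = occ, populations = poptab, truth = truth)
  attr(out, "truth") <- truth
  out
}

#' Default occurrence-fixture configuration
#'
#' @return named list understood by [make_occurrence_fixture()].
#' @export
default_occurrence_config <- function() {
  list(n_points = 60, n_duplicates = 20,
       lon_range = c(120.9, 121.7), lat_range = c(21.9, 24.4),
       grid_size = 0.05,
       species = c("playfairii", "tashiroi"))
}

#' Generate an occurrence table with in-cell duplicates
#'
#' Random occurrence points in a bounding box, plus records duplicated
#' inside the same grid cell (the situation the grid-deduplication
#' step removes).
#'
#' @param config list overriding [default_occurrence_config()].
#' @param seed RNG seed.
#' @return tibble: species, lon, lat, is_duplicate flag; `truth`
#'   attribute holds the grid size.
#' @export
make_occurrence_fixture <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_occurrence_config(), config)
  set.seed(seed)
  n <- cfg$n_points
  base <- tibble::tibble(
    species = sample(cfg$species, n, replace = TRUE),
    lon = runif(n, cfg$lon_range[1], cfg$lon_range[2]),
    lat = runif(n, cfg$lat_range[1], cfg$lat_range[2]),
    is_duplicate = FALSE)
  dup_src <- base[sample(n, cfg$n_duplicates, replace = TRUE), ]
  g <- cfg$grid_size
  dups <- dplyr::mutate(
    dup_src,
    lon = floor(.data$lon / g) * g + runif(dplyr::n(), 0, g * 0.999),
    lat = floor(.data$lat / g) * g + runif(dplyr::n(), 0, g * 0.999),
    is_duplicate = TRUE)
  out <- dplyr::bind_rows(base, dups)
  attr(out, "truth") <- list(grid_size = g, seed = seed,
                             n_base = n, n_duplicates = cfg$n_duplicates)
  out
}

#' Grid-deduplicate species occurrence records
#'
#' Keeps one record per species per grid cell (the first in row
#' order).
#'
#' @param occ tibble with species, lon, lat columns.
#' @param grid_size cell edge in degrees (> 0).
#' @return deduplicated tibble.
#' @export
dedup_occurrences <- function(occ, grid_size) {
  if (grid_size <= 0) stop("grid_size must be > 0", call. = FALSE)
  occ |>
    dplyr::mutate(.cell = paste(floor(.data$lon / grid_size),
                                floor(.data$lat / grid_size))) |>
    dplyr::distinct(.data$species, .data$.cell, .keep_all = TRUE) |>
    dplyr::select(-".cell")
}

#' Island-model allele counts for outlier-scan calibration
#'
#' Multinomial-Dirichlet draws around shared ancestral frequencies:
#' population frequencies ~ Dirichlet(theta p) with
#' `theta = 1/F_ST - 1`, counts multinomial. Optionally plants one
#' locus with fixed differences between two halves of the populations.
#'
#' @param n_loci neutral loci.
#' @param n_pops populations.
#' @param n_copies gene copies sampled per population.
#' @param fst island-model differentiation level.
#' @param n_alleles alleles per locus.
#' @param planted if TRUE, appends one locus fixed for different
#'   alleles in the two population groups.
#' @param seed RNG seed.
#' @return named list of population x allele count matrices.
#' @export
island_counts <- function(n_loci = 50, n_pops = 5, n_copies = 30,
                          fst = 0.05, n_alleles = 5, planted = FALSE,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- 1 / fst - 1
  out <- lapply(seq_len(n_loci), function(l) {
    p <- as.numeric(stats::rgamma(n_alleles, 1)); p <- p / sum(p)
    t(vapply(seq_len(n_pops), function(j) {
      pj <- as.numeric(stats::rgamma(n_alleles, theta * p))
      pj <- pj / sum(pj)
      as.integer(stats::rmultinom(1, n_copies, pj))
    }, integer(n_alleles)))
  })
  names(out) <- sprintf("neu%02d", seq_len(n_loci))
  if (planted) {
    half <- n_pops %/% 2
    m <- matrix(0L, n_pops, 2)
    m[seq_len(half), 1] <- n_copies
    m[(half + 1):n_pops, 2] <- n_copies
    out$planted <- m
  }
  out
}
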