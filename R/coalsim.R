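# Two-deme structured-coalescent microsatellite simulator.

#' Divergence scenario specification
#'
#' Describes one of four two-species divergence scenarios: complete
#' isolation (`CI`), ancestral migration (`AM`, gene flow only during
#' the initial divergence, i.e. in the backward-time window
#' `[t1, t2]`), secondary contact (`SC`, gene flow only recently, in
#' `[0, t1]`) and continuous migration (`CM`, gene flow throughout
#' `[0, t2]`). Time is in generations (the study species are annual
#' herbs, so generations equal years); `m12` is the fraction of deme 1
#' made of immigrants from deme 2 per generation and `m21` the
#' converse. Under the standard low-migration approximation the
#' backward lineage-migration rate equals the forward immigrant
#' fraction.
#'
#' @param model one of "CI", "AM", "SC", "CM".
#' @param n1,n2,n_anc diploid effective sizes of the two present demes
#'   and the ancestral deme.
#' @param t2 split time (generations before present).
#' @param t1 migration-epoch boundary, `0 <= t1 <= t2`.
#' @param m12,m21 immigrant fractions per generation (into deme 1 /
#'   into deme 2).
#' @param mu per-locus mutation rates (recycled to `n_loci` at
#'   simulation time).
#' @param p_geom geometric parameter of the generalized stepwise
#'   mutation model; 0 = strict single-step SMM.
#' @param f_is probability that an individual's second gene copy
#'   duplicates its first (inbreeding emulation).
#' @param sample_sizes list of two named integer vectors: diploid
#'   sample sizes of the labelled populations drawn from deme 1 and
#'   deme 2. Names of the list elements are used as species labels.
#' @return `ssr_scenario` object.
#' @export
scenario_spec <- function(model = c("CI", "AM", "SC", "CM"),
                          n1, n2, n_anc, t2, t1 = 0,
                          m12 = 0, m21 = 0,
                          mu = 5e-4, p_geom = 0, f_is = 0,
                          sample_sizes = list(
                            species1 = c(pop1 = 10),
                            species2 = c(pop2 = 10))) {
  model <- match.arg(model)
  if (t1 < 0 || t2 < 0 || t1 > t2) stop("need 0 <= t1 <= t2", call. = FALSE)
  if (any(c(m12, m21, mu) < 0)) stop("rates must be >= 0", call. = FALSE)
  if (p_geom < 0 || p_geom >= 1) stop("p_geom must be in [0, 1)", call. = FALSE)
  if (f_is < 0 || f_is > 1) stop("f_is must be in [0, 1]", call. = FALSE)
  if (length(sample_sizes) != 2) stop("sample_sizes must list two demes",
                                      call. = FALSE)
  if (any(unlist(sample_sizes) <= 0))
    stop("zero sample size in a sampled deme", call. = FALSE)
  structure(list(model = model, n1 = n1, n2 = n2, n_anc = n_anc,
                 t2 = t2, t1 = t1, m12 = m12, m21 = m21,
                 mu = mu, p_geom = p_geom, f_is = f_is,
                 sample_sizes = sample_sizes),
            class = "ssr_scenario")
}

#' @export
print.ssr_scenario <- function(x, ...) {
  cat("<ssr_scenario> ", x$model,
      sprintf(": N1=%g N2=%g Nanc=%g t2=%g t1=%g m12=%g m21=%g\n",
              x$n1, x$n2, x$n_anc, x$t2, x$t1, x$m12, x$m21))
  invisible(x)
}

#' Backward-time migration windows of a scenario
#'
#' CI has none; AM is active on `[t1, t2]`; SC on `[0, t1]`; CM on
#' `[0, t2]`. Zero-width windows are dropped, so `AM(t1 = t2)` and
#' `SC(t1 = 0)` both reduce to CI.
#'
#' @param spec [scenario_spec()] object.
#' @return tibble with columns start, end, m1 (backward rate of deme-1
#'   lineages, = `m12`), m2.
#' @export
migration_epochs <- function(spec) {
  stopifnot(inherits(spec, "ssr_scenario"))
  win <- switch(spec$model,
                CI = c(0, 0),
                AM = c(spec$t1, spec$t2),
                SC = c(0, spec$t1),
                CM = c(0, spec$t2))
  out <- tibble::tibble(start = win[1], end = win[2],
                        m1 = spec$m12, m2 = spec$m21)
  out[out$end > out$start, ]
}

#' Simulate a microsatellite dataset under a divergence scenario
#'
#' Continuous-time structured coalescent: pairwise coalescence at rate
#' `1/(2N)` per generation within a deme, backward lineage migration at
#' the forward immigrant fraction inside the scenario's windows, and a
#' single ancestral deme of size `n_anc` past `t2`. Mutations are
#' Poisson on branches; each shifts the allele state by a geometric
#' step (strict SMM at `p_geom = 0`), from ancestral state 100. Gene
#' copies are paired into diploids within demes; with probability
#' `f_is` an individual's second copy duplicates its first.
#'
#' @param spec [scenario_spec()] object.
#' @param n_loci number of loci (default: `length(spec$mu)` if > 1,
#'   else 1).
#' @param seed optional RNG seed.
#' @return [microsat_data()] object with population and species labels
#'   from `spec$sample_sizes`.
#' @export
simulate_dataset <- function(spec, n_loci = NULL, seed = NULL) {
  stopifnot(inherits(spec, "ssr_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n_loci <- n_loci %||% max(length(spec$mu), 1L)
  mu <- rep_len(spec$mu, n_loci)
  sizes1 <- spec$sample_sizes[[1]]; sizes2 <- spec$sample_sizes[[2]]
  nind1 <- sum(sizes1); nind2 <- sum(sizes2)
  ep <- as.matrix(migration_epochs(spec))
  if (nrow(ep) == 0) ep <- matrix(numeric(0), 0, 4)
  copies <- cpp_simulate_copies(2L * nind1, 2L * nind2,
                                spec$n1, spec$n2, spec$n_anc, spec$t2,
                                ep, mu, spec$p_geom)
  n <- nind1 + nind2
  a1 <- copies[seq(1, 2 * n, by = 2), , drop = FALSE]
  a2 <- copies[seq(2, 2 * n, by = 2), , drop = FALSE]
  if (spec$f_is > 0) {
    dup <- matrix(runif(n * n_loci) < spec$f_is, n, n_loci)
    a2[dup] <- a1[dup]
  }
  # keep states positive: recentre if any branch walked below 1
  lo <- min(c(a1, a2))
  if (lo < 1L) { a1 <- a1 - lo + 1L; a2 <- a2 - lo + 1L }
  alleles <- array(NA_integer_, c(n, n_loci, 2))
  alleles[, , 1] <- a1; alleles[, , 2] <- a2
  sp <- names(spec$sample_sizes) %||% c("species1", "species2")
  ind <- tibble::tibble(
    individual = sprintf("ind%03d", seq_len(n)),
    population = c(rep(names(sizes1), sizes1), rep(names(sizes2), sizes2)),
    species = c(rep(sp[1], nind1), rep(sp[2], nind2)))
  microsat_data(alleles, ind, sprintf("ssr%02d", seq_len(n_loci)))
}

#' Draw scenario parameters from declared priors
#'
#' Each prior is `list(dist, min, max)` with `dist` one of `"uniform"`,
#' `"loguniform"`, `"fixed"` (uses `min`), or `"uniform_frac_t2"`
#' (uniform on `[min, max]` as a fraction of the drawn `t2`, which
#' enforces `t1 <= t2`).
#'
#' @param priors named list of prior declarations.
#' @param n_draws number of independent draws.
#' @param seed optional RNG seed.
#' @return tibble of draws, one column per parameter.
#' @export
draw_from_priors <- function(priors, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function(p, n, t2 = NULL) {
    if (!is.null(p$min) && !is.null(p$max) && p$min > p$max)
      stop("inverted prior bounds", call. = FALSE)
    switch(p$dist,
           uniform = runif(n, p$min, p$max),
           loguniform = exp(runif(n, log(p$min), log(p$max))),
           fixed = rep(p$min, n),
           uniform_frac_t2 = runif(n, p$min, p$max) * t2,
           loguniform_frac_t2 = exp(runif(n, log(p$min), log(p$max))) * t2,
           stop("unknown prior dist: ", p$dist, call. = FALSE))
  }
  # draw t2 first so conditional priors can see it
  ord <- names(priors)
  out <- list()
  if ("t2" %in% ord) out$t2 <- draw1(priors$t2, n_draws)
  for (nm in setdiff(ord, "t2"))
    out[[nm]] <- draw1(priors[[nm]], n_draws, t2 = out$t2)
  tibble::as_tibble(out)[, ord]
}

#' Default priors for ABC inference
#'
#' Uniform effective sizes and migration fractions; log-uniform split
#' time, mutation rate, and epoch boundary (as a fraction of `t2`,
#' which enforces `t1 <= t2`). Time-scale parameters get log-uniform
#' priors because the observable consequences of an epoch boundary
#' depend on its ratio to the coalescent timescale, which spans orders
#' of magnitude across the prior range.
#'
#' @return named list of prior declarations for [draw_from_priors()].
#' @export
default_priors <- function() {
  list(
    N1   = list(dist = "uniform", min = 100, max = 1000),
    N2   = list(dist = "uniform", min = 100, max = 1000),
    Nanc = list(dist = "uniform", min = 100, max = 1000),
    t2   = list(dist = "loguniform", min = 1e4, max = 5e5),
    t1   = list(dist = "loguniform_frac_t2", min = 1e-3, max = 1),
    m12  = list(dist = "uniform", min = 0, max = 0.2),
    m21  = list(dist = "uniform", min = 0, max = 0.2),
    mu   = list(dist = "loguniform", min = 1e-4, max = 1e-3))
}

# build a concrete scenario from one prior draw
scenario_from_draw <- function(model, draw, sample_sizes,
                               p_geom = 0, f_is = 0) {
  m12 <- if (model == "CI") 0 else draw$m12
  m21 <- if (model == "CI") 0 else draw$m21
  scenario_spec(model, n1 = draw$N1, n2 = draw$N2, n_anc = draw$Nanc,
                t2 = draw$t2, t1 = draw$t1, m12 = m12, m21 = m21,
                mu = draw$mu, p_geom = p_geom, f_is = f_is,
                sample_sizes = sample_sizes)
}
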