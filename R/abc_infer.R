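# ABC model choice and parameter estimation.

#' Summary statistics of a microsatellite dataset
#'
#' Per population: mean allele count `K`, mean expected heterozygosity
#' `H`, mean allele-size variance `V`, mean Garza-Williamson
#' `M = alleles / (size range + 1)`; per population pair: AMOVA-style
#' identity FST, squared difference of mean allele sizes `dmu2`, and
#' the proportion of shared alleles (Jaccard overlap of allele sets),
#' each averaged across loci. Missing copies are excluded. Undefined
#' pairwise FST (e.g. on monomorphic data) is replaced by 0 with a
#' warning.
#'
#' @param ds [microsat_data()] object with >= 2 populations.
#' @return named numeric vector of statistics.
#' @export
summary_stats <- function(ds) {
  assert_ssr_geno(ds)
  pops <- unique(ds$individuals$population)
  if (length(pops) < 2) stop("need >= 2 populations", call. = FALSE)
  al <- copies_matrix(ds)
  pop_idx <- rep(match(ds$individuals$population, pops), each = 2L) - 1L
  s <- cpp_sumstats(al, pop_idx, length(pops))
  if (anyNA(s)) {
    warning("undefined F_ST replaced by 0 (monomorphic comparison)",
            call. = FALSE)
    s[is.na(s)] <- 0
  }
  s
}

#' Build an ABC reference table
#'
#' Draws parameters from the priors, simulates a dataset under every
#' requested scenario for each draw set, and records the summary
#' statistics. Population / sample-size layout is taken from
#' `sample_sizes` (the observed design).
#'
#' @param models character vector of scenario labels (subset of
#'   CI/AM/SC/CM).
#' @param priors prior list, see [draw_from_priors()].
#' @param sample_sizes two-deme sample-size layout, see
#'   [scenario_spec()].
#' @param n_loci loci per simulated dataset.
#' @param n_sims simulations per model.
#' @param seed RNG seed for the whole table.
#' @param p_geom,f_is mutation-step and inbreeding settings passed to
#'   the simulator.
#' @return tibble: model, parameter columns, statistic columns
#'   (statistics prefixed `S_`).
#' @export
build_reference_table <- function(models, priors, sample_sizes,
                                  n_loci = 15, n_sims = 1000, seed = NULL,
                                  p_geom = 0, f_is = 0) {
  if (!is.null(seed)) set.seed(seed)
  sizes1 <- sample_sizes[[1]]; sizes2 <- sample_sizes[[2]]
  n1c <- 2L * sum(sizes1); n2c <- 2L * sum(sizes2)
  npop <- length(sizes1) + length(sizes2)
  pop_of_copy <- rep(seq_len(npop), 2L * c(sizes1, sizes2)) - 1L
  out <- vector("list", length(models))
  for (mi in seq_along(models)) {
    model <- models[mi]
    draws <- draw_from_priors(priors, n_sims)
    rows <- vector("list", n_sims)
    for (i in seq_len(n_sims)) {
      d <- draws[i, ]
      win <- switch(model, CI = c(0, 0), AM = c(d$t1, d$t2),
                    SC = c(0, d$t1), CM = c(0, d$t2))
      ep <- if (model == "CI" || win[2] <= win[1])
        matrix(numeric(0), 0, 4)
      else matrix(c(win, d$m12, d$m21), 1, 4)
      copies <- cpp_simulate_copies(n1c, n2c, d$N1, d$N2, d$Nanc, d$t2,
                                    ep, rep(d$mu, n_loci), p_geom)
      if (f_is > 0) {
        i1 <- seq(1, nrow(copies), 2)
        dup <- matrix(runif(length(i1) * n_loci) < f_is,
                      length(i1), n_loci)
        c2 <- copies[i1 + 1L, , drop = FALSE]
        c1 <- copies[i1, , drop = FALSE]
        c2[dup] <- c1[dup]
        copies[i1 + 1L, ] <- c2
      }
      s <- cpp_sumstats(copies, pop_of_copy, npop)
      s[is.na(s)] <- 0
      rows[[i]] <- s
    }
    stats <- do.call(rbind, rows)
    colnames(stats) <- paste0("S_", colnames(stats))
    out[[mi]] <- dplyr::bind_cols(
      tibble::tibble(model = model), draws, tibble::as_tibble(stats))
  }
  dplyr::bind_rows(out)
}

stat_cols_of <- function(ref) grep("^S_", names(ref), value = TRUE)
param_cols_of <- function(ref)
  setdiff(names(ref)[vapply(ref, is.numeric, logical(1))], stat_cols_of(ref))

# marginal Box-Cox: profile-likelihood lambda on a shifted positive
# variable, as MASS::boxcox does for an intercept-only model.
fit_boxcox <- function(x) {
  shift <- if (min(x) <= 0) 1e-6 - min(x) else 0
  xs <- x + shift
  bc <- MASS::boxcox(xs ~ 1, data = data.frame(xs = xs),
                     lambda = seq(-2, 2, 0.05), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  list(lambda = lambda, shift = shift)
}

apply_boxcox <- function(x, tr) {
  xs <- x + tr$shift
  xs[xs <= 0] <- 1e-12   # guard for new values beyond the reference range
  if (abs(tr$lambda) < 1e-8) log(xs) else (xs^tr$lambda - 1) / tr$lambda
}

#' Box-Cox transform and partial-least-squares reduction
#'
#' Every statistic column of the reference table is Box-Cox
#' transformed (lambda fitted per statistic on the reference, with a
#' shift for non-positive values), standardized, and the set is
#' reduced by a PLS regression of the parameters on the statistics.
#' The loadings fitted on the reference are applied identically to the
#' observed statistics. Constant statistic columns are dropped with a
#' warning before the transform.
#'
#' @param ref reference table from [build_reference_table()].
#' @param observed named vector of observed statistics (names as
#'   returned by [summary_stats()], with or without the `S_` prefix).
#' @param n_components number of PLS components to retain.
#' @return `ssr_pls` object with `ref_scores` (matrix), `obs_scores`,
#'   and the transform parameters.
#' @export
boxcox_pls <- function(ref, observed, n_components = 5) {
  scols <- stat_cols_of(ref)
  pcols <- setdiff(param_cols_of(ref), "model")
  if (length(scols) == 0) stop("no statistic (S_*) columns", call. = FALSE)
  if (n_components > length(scols))
    stop("n_components exceeds the number of statistics", call. = FALSE)
  if (nrow(ref) < 10 * n_components)
    stop("reference table too small for ", n_components, " components",
         call. = FALSE)
  names(observed) <- ifelse(grepl("^S_", names(observed)),
                            names(observed), paste0("S_", names(observed)))
  if (!all(scols %in% names(observed)))
    stop("observed statistics missing: ",
         paste(setdiff(scols, names(observed)), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(ref[, scols])
  keep <- apply(X, 2, function(x) stats::sd(x) > 1e-10)
  if (!all(keep)) {
    warning("dropping constant statistic column(s): ",
            paste(scols[!keep], collapse = ", "), call. = FALSE)
    scols <- scols[keep]
    X <- X[, scols, drop = FALSE]
  }
  trs <- lapply(seq_len(ncol(X)), function(j) fit_boxcox(X[, j]))
  Xt <- vapply(seq_len(ncol(X)), function(j) apply_boxcox(X[, j], trs[[j]]),
               numeric(nrow(X)))
  ctr <- colMeans(Xt); scl <- apply(Xt, 2, stats::sd)
  Xs <- scale(Xt, center = ctr, scale = scl)
  colnames(Xs) <- scols
  Y <- as.matrix(ref[, pcols])
  fit <- mixOmics::pls(Xs, Y, ncomp = n_components, mode = "regression",
                       scale = FALSE)
  obs <- observed[scols]
  obs_t <- vapply(seq_along(scols), function(j)
    apply_boxcox(obs[j], trs[[j]]), numeric(1))
  obs_s <- (obs_t - ctr) / scl
  # NIPALS scores use successively deflated X; project new points with
  # the rotation matrix R = W (P'W)^-1 so they land in the same space
  W <- fit$loadings$X
  P <- crossprod(fit$X, fit$variates$X) %*%
    diag(1 / colSums(fit$variates$X^2), n_components)
  R <- W %*% solve(crossprod(P, W))
  obs_scores <- drop(obs_s %*% R)
  structure(list(
    ref_scores = fit$variates$X,
    obs_scores = obs_scores,
    rotation = R, transforms = trs, center = ctr, scale = scl,
    stat_cols = scols, param_cols = pcols, model = ref$model,
    n_components = n_components),
    class = "ssr_pls")
}

#' Rejection step: retain the closest simulations
#'
#' Euclidean distance in the reduced component space; exactly `n_keep`
#' smallest distances retained, ties broken by row order.
#'
#' @param pls `ssr_pls` object from [boxcox_pls()], or a list with
#'   `ref_scores` and `obs_scores`.
#' @param n_keep number of rows to retain.
#' @param subset optional logical/integer subset of reference rows to
#'   rank (e.g. one model's rows).
#' @return tibble: `index` (row in the reference table), `distance`.
#' @export
abc_reject <- function(pls, n_keep = 5000, subset = NULL) {
  if (n_keep <= 0) stop("n_keep must be positive", call. = FALSE)
  sc <- pls$ref_scores
  idx <- seq_len(nrow(sc))
  if (!is.null(subset)) idx <- idx[subset]
  if (n_keep > length(idx)) stop("n_keep exceeds available rows",
                                 call. = FALSE)
  d <- sqrt(colSums((t(sc[idx, , drop = FALSE]) - pls$obs_scores)^2))
  ord <- order(d, seq_along(d))[seq_len(n_keep)]
  tibble::tibble(index = idx[ord], distance = d[ord])
}

#' GLM post-sampling adjustment and marginal density
#'
#' ABC-GLM: on the retained simulations fit the multivariate linear
#' model `stats = c + B params + eps` with multivariate-normal
#' residuals, then average the likelihood of the observed statistics
#' over the retained prior sample:
#' `MD = mean_i N(obs; c + B theta_i, Sigma)`. The same per-draw
#' likelihoods serve as importance weights for the parameter
#' posterior. A singular residual covariance is ridge-regularized with
#' a logged jitter.
#'
#' @param params matrix/data frame of retained parameter draws.
#' @param stats matrix of the retained rows' statistics (component
#'   scores).
#' @param observed observed statistic vector in the same space.
#' @return `ssr_glmfit` list: `marginal_density`, `weights` (normalized),
#'   `params`, `coef`, `sigma`.
#' @export
glm_adjust <- function(params, stats, observed) {
  params <- as.matrix(params)
  stats <- as.matrix(stats)
  if (nrow(params) < 10 * ncol(params))
    stop("too few retained rows for the GLM adjustment", call. = FALSE)
  X <- cbind(1, params)
  fit <- stats::lm.fit(X, stats)
  res <- as.matrix(fit$residuals)
  Sigma <- crossprod(res) / (nrow(stats) - ncol(X))
  eg <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) < 1e-10 * max(eg)) {
    jit <- 1e-8 * max(max(eg), 1)
    message("singular residual covariance; ridge jitter ", signif(jit, 3),
            " added")
    Sigma <- Sigma + diag(jit, ncol(Sigma))
  }
  pred <- X %*% fit$coefficients
  dev <- sweep(pred, 2, observed)
  ll <- mvtnorm::dmvnorm(dev, sigma = Sigma, log = TRUE)
  md <- mean(exp(ll))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  structure(list(marginal_density = md, weights = w,
                 params = tibble::as_tibble(as.data.frame(params)),
                 coef = fit$coefficients, sigma = Sigma),
            class = "ssr_glmfit")
}

#' Model choice from per-model marginal densities
#'
#' Relative density = each model's marginal density as a percentage of
#' the sum (the model posterior under equal model priors); the Bayes
#' factor matrix holds all pairwise density ratios.
#'
#' @param md named vector of marginal densities (>= 2 models).
#' @return `ssr_abc` object.
#' @export
model_choice <- function(md) {
  if (length(md) < 2) stop("need >= 2 models", call. = FALSE)
  if (all(md == 0)) stop("all marginal densities are zero; observed ",
                         "statistics lie outside every model's support",
                         call. = FALSE)
  rd <- 100 * md / sum(md)
  bf <- outer(md, md, "/")
  structure(list(
    table = tibble::tibble(model = names(md), marginal_density = unname(md),
                           relative_density = unname(rd)),
    bayes_factors = bf, best = names(md)[which.max(md)]),
    class = "ssr_abc")
}

#' @export
print.ssr_abc <- function(x, ...) {
  cat("ABC model choice; best model:", x$best, "\n")
  print(x$table)
  invisible(x)
}

#' Posterior summaries from (weighted) draws
#'
#' Mode from a Gaussian kernel density argmax on a 512-point grid,
#' weighted median, and highest-posterior-density intervals (shortest
#' interval holding the mass) at 50% and 95%.
#'
#' @param draws numeric vector (or data frame of parameters).
#' @param weights optional importance weights.
#' @return tibble: parameter, mode, median, hpd50_lo/hi, hpd95_lo/hi.
#' @export
posterior_summarize <- function(draws, weights = NULL) {
  if (is.data.frame(draws) || is.matrix(draws)) {
    draws <- as.data.frame(draws)
    out <- lapply(names(draws), function(nm) {
      dplyr::mutate(posterior_summarize(draws[[nm]], weights),
                    parameter = nm, .before = 1)
    })
    return(dplyr::bind_rows(out))
  }
  n <- length(draws)
  w <- weights %||% rep(1 / n, n)
  w <- w / sum(w)
  if (n < 100) warning("fewer than 100 draws; summaries are rough",
                       call. = FALSE)
  if (stats::sd(draws) < 1e-12) {
    v <- draws[1]
    return(tibble::tibble(parameter = NA_character_, mode = v, median = v,
                          hpd50_lo = v, hpd50_hi = v,
                          hpd95_lo = v, hpd95_hi = v))
  }
  d <- stats::density(draws, weights = w, n = 512)
  mode <- d$x[which.max(d$y)]
  ord <- order(draws)
  x <- draws[ord]; cw <- cumsum(w[ord])
  wmedian <- x[which(cw >= 0.5)[1]]
  hpd <- function(level) {
    # shortest interval with >= level mass (two-pointer on sorted draws)
    best <- c(x[1], x[n]); bw <- Inf
    j <- 1
    for (i in seq_len(n)) {
      while (j <= n && (cw[j] - (if (i > 1) cw[i - 1] else 0)) < level) j <- j + 1
      if (j > n) break
      if (x[j] - x[i] < bw) { bw <- x[j] - x[i]; best <- c(x[i], x[j]) }
    }
    best
  }
  h50 <- hpd(0.5); h95 <- hpd(0.95)
  tibble::tibble(parameter = NA_character_, mode = mode, median = wmedian,
                 hpd50_lo = h50[1], hpd50_hi = h50[2],
                 hpd95_lo = h95[1], hpd95_hi = h95[2])
}

#' End-to-end ABC model choice
#'
#' Pools the reference table across models, fits one Box-Cox + PLS
#' transformation (model choice needs a common space), retains the
#' `n_keep` best simulations per model, computes each model's
#' GLM marginal density, and normalizes.
#'
#' @param ref reference table from [build_reference_table()].
#' @param observed observed summary-statistic vector.
#' @param n_components PLS components.
#' @param n_keep retained simulations per model.
#' @return `ssr_abc` object; per-model `ssr_glmfit`s in `$fits`.
#' @export
abc_model_choice <- function(ref, observed, n_components = 5,
                             n_keep = 5000) {
  pls <- boxcox_pls(ref, observed, n_components)
  models <- unique(ref$model)
  fits <- list()
  md <- setNames(numeric(length(models)), models)
  for (m in models) {
    sel <- ref$model == m
    kept <- abc_reject(pls, n_keep = min(n_keep, sum(sel)), subset = sel)
    fits[[m]] <- glm_adjust(ref[kept$index, pls$param_cols],
                            pls$ref_scores[kept$index, , drop = FALSE],
                            pls$obs_scores)
    md[m] <- fits[[m]]$marginal_density
  }
  out <- model_choice(md)
  out$fits <- fits
  out
}
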