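# FST outlier detection: multinomial-Dirichlet model, reversible-jump MCMC.

#' Fit the FST outlier model by reversible-jump MCMC
#'
#' BayeScan-type decomposition of locus-by-population FST into a
#' locus effect `alpha_i` (selection) and a population effect `beta_j`
#' (demography) on the logit scale; observed allele counts are
#' multinomial-Dirichlet around ancestral frequencies with
#' `theta_ij = 1/F_ij - 1`. A reversible jump toggles each locus's
#' `alpha_i` in and out of the model against prior odds for
#' neutrality, so each locus's posterior inclusion probability
#' measures the evidence for selection.
#'
#' @param ds [microsat_data()] object (>= 2 populations, >= 2 loci), or
#'   a list of per-locus population x allele count matrices.
#' @param iterations post-burn-in iterations (paper-scale default 1e5).
#' @param thinning thinning interval for retained states.
#' @param burn_in burn-in iterations.
#' @param prior_odds prior odds for neutrality (10 calibrates the
#'   "PO > 10" decision rule).
#' @param seed optional RNG seed.
#' @param sd_alpha_prior,sd_beta_prior prior scales of the locus and
#'   population effects.
#' @return `ssr_outlier_chain`: thinned samples of alpha, inclusion,
#'   beta and the log-likelihood trace.
#' @export
fit_outlier_scan <- function(ds, iterations = 1e5, thinning = 1000,
                             burn_in = 5e4, prior_odds = 10, seed = NULL,
                             sd_alpha_prior = 1, sd_beta_prior = 1) {
  if (inherits(ds, "ssr_geno")) {
    if (length(unique(ds$individuals$population)) < 2)
      stop("F_ST is undefined for a single population", call. = FALSE)
    cms <- count_matrices(ds)
    names(cms) <- ds$loci
  } else {
    cms <- ds
    if (nrow(cms[[1]]) < 2)
      stop("F_ST is undefined for a single population", call. = FALSE)
  }
  loci <- names(cms) %||% sprintf("L%02d", seq_along(cms))
  poly <- vapply(cms, function(m) ncol(m) >= 2, logical(1))
  if (!all(poly)) {
    warning("excluding monomorphic locus/loci: ",
            paste(loci[!poly], collapse = ", "), call. = FALSE)
    cms <- cms[poly]; loci <- loci[poly]
  }
  if (length(cms) < 2) stop("need >= 2 polymorphic loci", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_outlier_scan(unname(cms), as.integer(iterations),
                          as.integer(burn_in), as.integer(thinning),
                          prior_odds, sd_alpha_prior, sd_beta_prior,
                          0.2, 0.25, 1.0, 0.05)
  if (any(!is.finite(res$loglik)))
    stop("non-finite likelihood in chain; state dump attached",
         call. = FALSE)
  colnames(res$alpha) <- colnames(res$included) <- loci
  structure(list(alpha = res$alpha, included = res$included,
                 beta = res$beta, loglik = res$loglik,
                 acc_rates = res$acc_rates, loci = loci,
                 prior_odds = prior_odds,
                 settings = list(iterations = iterations,
                                 burn_in = burn_in, thinning = thinning)),
            class = "ssr_outlier_chain")
}

#' @export
print.ssr_outlier_chain <- function(x, ...) {
  cat("<ssr_outlier_chain> ", length(x$loci), " loci, ",
      nrow(x$alpha), " retained states\n", sep = "")
  cat("acceptance rates: ",
      paste(names(x$acc_rates), round(x$acc_rates, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify outlier loci from a fitted chain
#'
#' Posterior odds `PO = P(included) / (1 - P(included))` (capped at
#' 9999 when a locus is never excluded), q-values as the cumulative
#' mean of the sorted posterior neutrality probabilities, and a
#' three-way class: `positive` (flagged, mean alpha > 0), `balancing`
#' (flagged, mean alpha < 0), else `neutral`. A locus is flagged when
#' `PO > po_threshold` and `q < q_threshold`.
#'
#' @param chain `ssr_outlier_chain` from [fit_outlier_scan()].
#' @param po_threshold posterior-odds threshold (default 10, i.e.
#'   posterior probability 0.90).
#' @param q_threshold false-discovery-rate threshold.
#' @return `ssr_outlier` tibble: locus, p_included, po, alpha, qvalue,
#'   class.
#' @export
classify_outliers <- function(chain, po_threshold = 10, q_threshold = 0.05) {
  stopifnot(inherits(chain, "ssr_outlier_chain"))
  if (po_threshold <= 0) stop("po_threshold must be in (0, Inf)",
                              call. = FALSE)
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)", call. = FALSE)
  if (nrow(chain$alpha) < 2) stop("need >= 2 retained states", call. = FALSE)
  p_incl <- unname(colMeans(chain$included))
  alpha <- unname(colMeans(chain$alpha))
  po <- ifelse(p_incl >= 1, 9999, p_incl / (1 - p_incl))
  if (any(p_incl >= 1))
    message("PO capped at 9999 for ",
            paste(chain$loci[p_incl >= 1], collapse = ", "))
  p_neutral <- 1 - p_incl
  ord <- order(p_neutral)
  q <- cummean <- cumsum(p_neutral[ord]) / seq_along(ord)
  qvalue <- numeric(length(q)); qvalue[ord] <- q
  flagged <- po > po_threshold & qvalue < q_threshold
  out <- tibble::tibble(
    locus = chain$loci, p_included = p_incl, po = po, alpha = alpha,
    qvalue = qvalue,
    class = dplyr::case_when(
      flagged & alpha > 0 ~ "positive",
      flagged & alpha < 0 ~ "balancing",
      TRUE ~ "neutral"))
  class(out) <- c("ssr_outlier", class(out))
  out
}

#' Split loci by outlier class
#'
#' @param ds [microsat_data()] object.
#' @param report `ssr_outlier` tibble from [classify_outliers()].
#' @return list of `ssr_geno` subsets: total, neutral, positive,
#'   balancing (absent classes dropped).
#' @export
split_loci <- function(ds, report) {
  assert_ssr_geno(ds)
  pick <- function(loci) {
    if (length(loci) == 0) return(NULL)
    sel <- match(loci, ds$loci)
    microsat_data(ds$alleles[, sel, , drop = FALSE], ds$individuals,
                  ds$loci[sel])
  }
  out <- list(
    total = ds,
    neutral = pick(report$locus[report$class == "neutral"]),
    positive = pick(report$locus[report$class == "positive"]),
    balancing = pick(report$locus[report$class == "balancing"]))
  out[!vapply(out, is.null, logical(1))]
}
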