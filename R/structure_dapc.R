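# Bayesian admixture clustering, Evanno delta-K, run alignment, DAPC.

#' Bayesian admixture clustering (correlated allele frequencies)
#'
#' Gibbs sampler for the admixture model: every gene copy is assigned
#' to a cluster given the individual's admixture proportions `Q` and
#' the cluster allele frequencies; cluster frequencies are drawn from
#' their Dirichlet full conditional around ancestral frequencies with
#' per-cluster drift `F_k` (the correlated-frequency prior); `Q` rows
#' are Dirichlet(alpha + counts). The Dirichlet parameter alpha gets a
#' Metropolis step with a uniform prior on (0, 10); the frequency
#' prior lambda is fixed at 1. `lnP(K)` is estimated as the mean
#' log-likelihood minus half its variance, the quantity the Evanno
#' delta-K consumes.
#'
#' @param ds [microsat_data()] object.
#' @param k number of clusters (>= 1).
#' @param burn_in,iterations MCMC lengths (test scale 5e3 + 2e4 by
#'   default; the study scale is 1e5 + 1e6).
#' @param seed optional RNG seed.
#' @param alpha_init initial admixture parameter.
#' @return `ssr_structure`: posterior-mean `Q` (tibble), `lnP`, drift
#'   `F`, `K`, seed and convergence flag (linear trend in the
#'   log-likelihood trace).
#' @export
admixture_mcmc <- function(ds, k, burn_in = 5000, iterations = 20000,
                           seed = NULL, alpha_init = 1) {
  assert_ssr_geno(ds)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cm <- copies_matrix(ds)
  # recode alleles per locus to 0-based dense indices
  nall <- integer(ncol(cm))
  for (l in seq_len(ncol(cm))) {
    lv <- sort(unique(cm[!is.na(cm[, l]), l]))
    nall[l] <- length(lv)
    cm[, l] <- match(cm[, l], lv) - 1L
  }
  cm[is.na(cm)] <- -1L
  if (k > max(nall))
    warning("k exceeds the allele count at every locus", call. = FALSE)
  res <- cpp_admixture(cm, nall, nrow(ds$individuals), as.integer(k),
                       as.integer(burn_in), as.integer(iterations),
                       alpha_init, 10, 0.1, 1, 0.1, 0.3, 0.05)
  Q <- res$Q
  colnames(Q) <- sprintf("cluster%d", seq_len(k))
  q_tbl <- dplyr::bind_cols(ds$individuals, tibble::as_tibble(Q))
  structure(list(Q = Q, q_table = q_tbl, K = k, lnP = res$lnP,
                 mean_loglik = res$mean_loglik,
                 var_loglik = res$var_loglik,
                 F = res$F, alpha = res$alpha, seed = seed),
            class = "ssr_structure")
}

#' @export
print.ssr_structure <- function(x, ...) {
  cat(sprintf("<ssr_structure> K = %d, lnP(K) = %.2f, alpha = %.3f\n",
              x$K, x$lnP, x$alpha))
  invisible(x)
}

#' Evanno delta-K table
#'
#' From replicate runs grouped by K: `ln'(K)` = difference of mean
#' `lnP(K)` to the previous K, `|ln''(K)|` = absolute difference of
#' successive `ln'`, and `deltaK = |ln''(K)| / sd(lnP(K))`. Delta-K is
#' defined only for interior K of a consecutive range.
#'
#' @param runs list of `ssr_structure` runs (several seeds per K over
#'   a consecutive K range of length >= 3).
#' @return `ssr_deltak` tibble: k, n_runs, mean_lnp, sd_lnp, lnp1,
#'   lnp2, delta_k.
#' @export
evanno_deltak <- function(runs) {
  ks <- vapply(runs, function(r) r$K, numeric(1))
  lnp <- vapply(runs, function(r) r$lnP, numeric(1))
  tab <- tibble::tibble(k = ks, lnp = lnp) |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(n_runs = dplyr::n(), mean_lnp = mean(.data$lnp),
                     sd_lnp = stats::sd(.data$lnp), .groups = "drop") |>
    dplyr::arrange(.data$k)
  if (nrow(tab) < 3) stop("need a consecutive K range of length >= 3",
                          call. = FALSE)
  if (!all(diff(tab$k) == 1)) stop("missing K in range", call. = FALSE)
  tab$lnp1 <- c(NA, diff(tab$mean_lnp))
  tab$lnp2 <- c(NA, abs(diff(tab$lnp1))[-1], NA)
  zero_sd <- !is.na(tab$lnp2) & tab$sd_lnp == 0
  if (any(zero_sd & tab$lnp2 > 0))
    warning("sd(lnP) = 0 for some K; delta-K infinite there", call. = FALSE)
  tab$delta_k <- ifelse(zero_sd, ifelse(tab$lnp2 == 0, 0, Inf),
                        tab$lnp2 / tab$sd_lnp)
  class(tab) <- c("ssr_deltak", class(tab))
  tab
}

# greedy column matching between two Q matrices: repeatedly pair the
# columns with the largest dot product.
match_columns <- function(ref, q) {
  K <- ncol(ref)
  sim <- crossprod(ref, q)  # sim[i, j] = ref_i . q_j
  perm <- integer(K)
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(sim), dim(sim))
    perm[ij[1]] <- ij[2]
    sim[ij[1], ] <- -Inf; sim[, ij[2]] <- -Inf
  }
  perm
}

#' Align replicate clustering runs (label switching)
#'
#' Greedy column-permutation alignment of each run onto the first,
#' maximizing the summed matched-column dot products (the CLUMPP G'
#' contract), then averaging.
#'
#' @param runs list of `ssr_structure` runs at the same K over the
#'   same individuals.
#' @return list: `aligned` (list of permuted Q matrices),
#'   `permutations`, `mean_q` (matrix).
#' @export
align_runs <- function(runs) {
  ks <- vapply(runs, function(r) r$K, numeric(1))
  if (length(unique(ks)) != 1) stop("runs differ in K", call. = FALSE)
  ids <- lapply(runs, function(r) r$q_table$individual)
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("inconsistent individual ordering across runs", call. = FALSE)
  ref <- runs[[1]]$Q
  perms <- lapply(runs, function(r) match_columns(ref, r$Q))
  aligned <- Map(function(r, p) r$Q[, p, drop = FALSE], runs, perms)
  aligned <- lapply(aligned, function(m) {
    colnames(m) <- colnames(ref); m
  })
  mean_q <- Reduce(`+`, aligned) / length(aligned)
  list(aligned = aligned, permutations = perms, mean_q = mean_q)
}

# individual x allele one-hot count matrix (0/1/2), missing copies
# contribute nothing; columns with zero variance dropped by callers.
allele_count_matrix <- function(ds) {
  cm <- copies_matrix(ds)
  n <- nrow(ds$individuals)
  cols <- list()
  for (l in seq_len(ncol(cm))) {
    lv <- sort(unique(cm[!is.na(cm[, l]), l]))
    for (a in lv) {
      v <- (cm[, l] == a)
      v[is.na(v)] <- FALSE
      cols[[paste0(ds$loci[l], ".", a)]] <-
        v[seq(1, 2 * n, 2)] + v[seq(2, 2 * n, 2)]
    }
  }
  do.call(cbind, cols)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Individuals' one-hot allele counts are centered and decomposed by
#' PCA; the leading `n_pcs` synthetic variables then feed a linear
#' discriminant analysis on the group labels, minimizing within-group
#' variation.
#'
#' @param ds [microsat_data()] object.
#' @param groups `"species"` or `"population"`.
#' @param n_pcs retained principal components (default 2).
#' @return `ssr_dapc`: individual coordinates (PCs and discriminant
#'   axes), group membership probabilities, assignment.
#' @export
dapc_fit <- function(ds, groups = c("species", "population"), n_pcs = 2) {
  assert_ssr_geno(ds)
  groups <- match.arg(groups)
  g <- factor(ds$individuals[[groups]],
              levels = unique(ds$individuals[[groups]]))
  if (any(table(g) < 2))
    stop("a group has a single individual; within-group scatter undefined",
         call. = FALSE)
  X <- allele_count_matrix(ds)
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  ld <- MASS::lda(scores, grouping = g)
  pr <- stats::predict(ld, scores)
  coords <- tibble::as_tibble(as.data.frame(scores))
  ldx <- as.data.frame(pr$x)
  memb <- pr$posterior
  out <- structure(list(
    individuals = ds$individuals,
    pc_scores = coords,
    ld_scores = tibble::as_tibble(ldx),
    membership = memb,
    assigned = as.character(pr$class),
    groups = as.character(g),
    n_pcs = n_pcs, var_explained = pc$sdev^2 / sum(pc$sdev^2),
    lda = ld),
    class = "ssr_dapc")
  out
}

#' @export
print.ssr_dapc <- function(x, ...) {
  acc <- mean(x$assigned == x$groups)
  cat(sprintf("<ssr_dapc> %d PCs, %d discriminant axes, %.1f%% correct\n",
              x$n_pcs, ncol(x$ld_scores), 100 * acc))
  invisible(x)
}
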