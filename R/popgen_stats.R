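# Per-population diversity statistics and hierarchical AMOVA.

#' Unbiased expected heterozygosity
#'
#' Small-sample correction `uHe = (2N / (2N - 1)) * He` for a sample of
#' `n` diploid individuals.
#'
#' @param he expected heterozygosity in `[0, 1]`.
#' @param n number of individuals (>= 1).
#' @return corrected heterozygosity.
#' @export
unbiased_he <- function(he, n) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(he < 0 | he > 1)) stop("`he` must be in [0, 1]", call. = FALSE)
  (2 * n / (2 * n - 1)) * he
}

# per-population per-locus statistics (internal substrate)
per_locus_stats <- function(ds) {
  freqs <- suppressWarnings(allele_frequencies(ds, by = "population"))
  freqs <- dplyr::filter(freqs, !is.na(.data$freq))
  byloc <- freqs |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(
      na = dplyr::n(),
      sump2 = sum(.data$freq^2),
      i = -sum(.data$freq * log(.data$freq)),
      n_copies = .data$n_copies[1],
      .groups = "drop") |>
    dplyr::mutate(ne = 1 / .data$sump2,
                  he = 1 - .data$sump2,
                  uhe = ifelse(.data$n_copies > 1,
                               .data$n_copies / (.data$n_copies - 1) * .data$he,
                               NA_real_))
  # observed heterozygosity per locus: among individuals with both copies
  ho <- as_tibble(ds) |>
    tidyr::pivot_wider(names_from = "copy", values_from = "allele",
                       names_prefix = "a") |>
    dplyr::filter(!is.na(.data$a1), !is.na(.data$a2)) |>
    dplyr::group_by(group = .data$population, locus = .data$locus) |>
    dplyr::summarise(ho = mean(.data$a1 != .data$a2), .groups = "drop")
  dplyr::left_join(byloc, ho, by = c("group", "locus"))
}

#' Per-population diversity table
#'
#' For every population, per-locus statistics are computed and then
#' averaged across loci (SE = across-locus standard deviation /
#' sqrt(number of loci)): `Na` observed alleles, `Ne = 1 / sum(p^2)`
#' effective alleles, Shannon index `I = -sum(p log p)`, observed (`Ho`)
#' and expected (`He = 1 - sum(p^2)`) heterozygosity, unbiased `uHe`
#' from [unbiased_he()] with the locus's non-missing sample size, and
#' the fixation index `F`, averaged over polymorphic loci only as
#' `1 - Ho/He` (monomorphic loci carry no information about `F`).
#'
#' @param ds [microsat_data()] object.
#' @return tibble, one row per population: `n` plus mean and `*_se`
#'   columns for na, ne, i, ho, he, uhe, f.
#' @export
diversity_table <- function(ds) {
  assert_ssr_geno(ds)
  pl <- per_locus_stats(ds) |>
    dplyr::mutate(f = ifelse(.data$he > 0, 1 - .data$ho / .data$he, NA_real_))
  mean_se <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = sd(x) / sqrt(length(x)))
  }
  nind <- dplyr::count(ds$individuals, population = .data$population,
                       name = "n")
  out <- pl |>
    dplyr::group_by(population = .data$group) |>
    dplyr::summarise(dplyr::across(
      c("na", "ne", "i", "ho", "he", "uhe", "f"),
      list(mean = ~mean_se(.x)[["mean"]], se = ~mean_se(.x)[["se"]])),
      .groups = "drop")
  names(out) <- sub("_mean$", "", names(out))
  out <- dplyr::left_join(nind, out, by = "population")
  # preserve input population order
  out[match(unique(ds$individuals$population), out$population), ]
}

# sums of squares within groups of gene copies, per locus, summed.
# alleles: copies x loci; grp: integer group index per copy.
# identity distance: SS_g = (N^2 - sum(c_a^2)) / (2N); squared-size:
# SS_g = sum(a^2) - (sum a)^2 / N  (pairwise (a_i - a_j)^2 / N form).
ss_within <- function(alleles, grp, distance = "identity") {
  tot <- 0
  for (l in seq_len(ncol(alleles))) {
    al <- alleles[, l]
    keep <- !is.na(al)
    a <- al[keep]; g <- grp[keep]
    if (distance == "identity") {
      for (gg in unique(g)) {
        x <- a[g == gg]; N <- length(x)
        if (N > 0) tot <- tot + (N^2 - sum(tabulate(match(x, unique(x)))^2)) / (2 * N)
      }
    } else {
      for (gg in unique(g)) {
        x <- a[g == gg]; N <- length(x)
        if (N > 0) tot <- tot + sum(x^2) - sum(x)^2 / N
      }
    }
  }
  tot
}

amova_components <- function(alleles, pop_idx, sp_of_pop, distance) {
  sp_idx <- sp_of_pop[pop_idx]
  N <- nrow(alleles)
  one <- rep(1L, N)
  ss_tot <- ss_within(alleles, one, distance)
  ss_ws  <- ss_within(alleles, sp_idx, distance)
  ss_wp  <- ss_within(alleles, pop_idx, distance)
  S <- length(unique(pop_idx)); G <- length(unique(sp_idx))
  Np <- tabulate(pop_idx); Ns <- tabulate(sp_idx)
  df <- c(G - 1, S - G, N - S)
  ss <- c(ss_tot - ss_ws, ss_ws - ss_wp, ss_wp)
  ms <- ifelse(df > 0, ss / df, 0)
  sum_np2_ns <- sum(vapply(seq_len(G), function(s)
    sum(Np[sp_of_pop == s]^2) / Ns[s], numeric(1)))
  n2 <- (sum_np2_ns - sum(Np^2) / N) / (G - 1)
  n3 <- (N - sum(Ns^2) / N) / (G - 1)
  sc <- ms[3]
  # every species holding a single population collapses the middle level
  sb <- if (S == G) 0 else (ms[2] - sc) / ((N - sum_np2_ns) / (S - G))
  sa <- (ms[1] - sc - n2 * sb) / n3
  list(df = df, ss = ss, sigma = c(a = sa, b = sb, c = sc))
}

f_from_sigma <- function(s) {
  tot <- sum(s)
  c(f_ct = s[[1]] / tot,
    f_sc = s[[2]] / (s[[2]] + s[[3]]),
    f_st = (s[[1]] + s[[2]]) / tot)
}

#' Hierarchical AMOVA (species / populations-within-species / within)
#'
#' Gene-copy-level nested analysis of molecular variance from pairwise
#' copy distances (identity by default; squared allele-size optionally),
#' with permutation tests: populations permuted among species (tests
#' `F_CT`), individuals among populations within species (`F_SC`), and
#' individuals among all populations (`F_ST`). Missing gene copies are
#' dropped from sums of squares; degrees of freedom follow the sampling
#' design (2 copies per individual). Negative variance components are
#' reported raw and flagged.
#'
#' @param ds [microsat_data()] object with >= 2 populations.
#' @param distance `"identity"` (FST-like, default) or `"size"`
#'   (squared allele-size, RST-like).
#' @param n_perm number of permutations per test.
#' @param seed optional RNG seed for the permutations.
#' @return `ssr_amova` object; see [tidy.ssr_amova()].
#' @export
amova <- function(ds, distance = c("identity", "size"), n_perm = 999,
                  seed = NULL) {
  assert_ssr_geno(ds)
  distance <- match.arg(distance)
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(ds$individuals$population)
  if (length(pops) < 2) stop("need >= 2 populations", call. = FALSE)
  sps <- unique(ds$individuals$species)
  pop_map <- unique(ds$individuals[, c("population", "species")])
  sp_of_pop <- match(pop_map$species, sps)[match(pops, pop_map$population)]
  if (any(tabulate(sp_of_pop, length(sps)) == 1))
    message("note: a species is represented by a single population; ",
            "F_SC permutation has limited resolution there")
  al <- copies_matrix(ds)
  ind_pop <- match(ds$individuals$population, pops)
  pop_idx <- rep(ind_pop, each = 2L)

  obs <- amova_components(al, pop_idx, sp_of_pop, distance)
  fobs <- f_from_sigma(obs$sigma)
  if (any(obs$sigma < 0))
    warning("negative variance component (reported raw)", call. = FALSE)

  # permutation tests
  n_ind <- nrow(ds$individuals)
  ge_ct <- ge_sc <- ge_st <- 0L
  for (b in seq_len(n_perm)) {
    # (a) populations among species
    perm_sp <- sample(sp_of_pop)
    f <- f_from_sigma(amova_components(al, pop_idx, perm_sp, distance)$sigma)
    ge_ct <- ge_ct + (f[["f_ct"]] >= fobs[["f_ct"]])
    # (b) individuals among populations within species
    perm_pop <- ind_pop
    for (s in seq_along(sps)) {
      sel <- which(sp_of_pop[ind_pop] == s)
      perm_pop[sel] <- sample(ind_pop[sel])
    }
    f <- f_from_sigma(amova_components(
      al, rep(perm_pop, each = 2L), sp_of_pop, distance)$sigma)
    ge_sc <- ge_sc + (f[["f_sc"]] >= fobs[["f_sc"]])
    # (c) individuals among all populations
    perm_pop <- sample(ind_pop)
    f <- f_from_sigma(amova_components(
      al, rep(perm_pop, each = 2L), sp_of_pop, distance)$sigma)
    ge_st <- ge_st + (f[["f_st"]] >= fobs[["f_st"]])
  }
  pvals <- (1 + c(ge_ct, ge_sc, ge_st)) / (n_perm + 1)

  pct <- 100 * obs$sigma / sum(obs$sigma)
  structure(list(
    table = tibble::tibble(
      source = c("Among species", "Among populations within species",
                 "Within populations", "Total"),
      df = c(obs$df, sum(obs$df)),
      ss = c(obs$ss, sum(obs$ss)),
      sigma = c(unname(obs$sigma), sum(obs$sigma)),
      pct_var = c(unname(pct), 100),
      f = c(fobs[["f_ct"]], fobs[["f_sc"]], fobs[["f_st"]], NA),
      p = c(pvals, NA)),
    f_ct = fobs[["f_ct"]], f_sc = fobs[["f_sc"]], f_st = fobs[["f_st"]],
    n_perm = n_perm, distance = distance),
    class = "ssr_amova")
}

#' @export
print.ssr_amova <- function(x, ...) {
  cat("AMOVA (", x$distance, " distance, ", x$n_perm, " permutations)\n",
      sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' F-statistics and percentages from published variance components
#'
#' Exact arithmetic on given variance components `sigma_a` (among
#' species), `sigma_b` (among populations within species) and `sigma_c`
#' (within populations): `F_CT = a/(a+b+c)`, `F_SC = b/(b+c)`,
#' `F_ST = (a+b)/(a+b+c)`, with percentages of total.
#'
#' @param sigma_a,sigma_b,sigma_c variance components.
#' @return tibble with percentages and the three F-statistics.
#' @export
amova_from_components <- function(sigma_a, sigma_b, sigma_c) {
  tot <- sigma_a + sigma_b + sigma_c
  if (tot == 0) stop("all variance components are zero", call. = FALSE)
  f <- f_from_sigma(c(sigma_a, sigma_b, sigma_c))
  tibble::tibble(
    pct_among_species = 100 * sigma_a / tot,
    pct_among_pops = 100 * sigma_b / tot,
    pct_within = 100 * sigma_c / tot,
    f_ct = f[["f_ct"]], f_sc = f[["f_sc"]], f_st = f[["f_st"]])
}

#' Pairwise population FST matrix
#'
#' AMOVA-style FST on identity distances for every population pair
#' (one-level variance partition per pair); symmetric with zero
#' diagonal. A pair sharing no scored locus gets `NA`.
#'
#' @param ds [microsat_data()] object.
#' @return symmetric matrix of pairwise FST.
#' @export
pairwise_fst <- function(ds) {
  assert_ssr_geno(ds)
  pops <- unique(ds$individuals$population)
  al <- copies_matrix(ds)
  pop_idx <- rep(match(ds$individuals$population, pops), each = 2L)
  K <- length(pops)
  out <- matrix(0, K, K, dimnames = list(pops, pops))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    sel <- pop_idx %in% c(a, b)
    out[a, b] <- out[b, a] <-
      two_group_fst(al[sel, , drop = FALSE], match(pop_idx[sel], c(a, b)))
  }
  out
}

# one-level AMOVA FST for exactly two groups of gene copies, identity
# distance, SS summed over loci, per-locus non-missing sample sizes
# averaged for the df / n0 coefficients (Arlequin-style).
two_group_fst <- function(alleles, grp) {
  SSw <- SStot <- 0; Nv <- Nav <- Nbv <- numeric(0)
  for (l in seq_len(ncol(alleles))) {
    al <- alleles[, l]
    keep <- !is.na(al)
    x <- al[keep]; g <- grp[keep]
    Na <- sum(g == 1); Nb <- sum(g == 2)
    if (Na < 1 || Nb < 1) next
    ssg <- function(v) {
      N <- length(v)
      (N^2 - sum(tabulate(match(v, unique(v)))^2)) / (2 * N)
    }
    SSw <- SSw + ssg(x[g == 1]) + ssg(x[g == 2])
    SStot <- SStot + ssg(x)
    Nv <- c(Nv, Na + Nb); Nav <- c(Nav, Na); Nbv <- c(Nbv, Nb)
  }
  if (length(Nv) == 0) return(NA_real_)
  N <- mean(Nv); Na <- mean(Nav); Nb <- mean(Nbv)
  if (N - 2 <= 0) return(NA_real_)
  MSw <- SSw / (N - 2)
  MSa <- SStot - SSw
  n0 <- N - (Na^2 + Nb^2) / N
  # negative pair estimates are truncated at zero (no differentiation)
  sa <- max((MSa - MSw) / n0, 0)
  tot <- sa + MSw
  if (tot <= 0) return(0)
  sa / tot
}
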