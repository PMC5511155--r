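test_that("K = 1 forces full membership in one cluster", {
  ds <- random_geno(seed = 5, n_per_pop = c(6, 6), miss = 0)
  r <- admixture_mcmc(ds, 1, burn_in = 200, iterations = 600, seed = 1)
  expect_equal(unname(r$Q[, 1]), rep(1, 12))
  expect_true(is.finite(r$lnP))
})

test_that("planted two-deme structure is recovered at K = 2", {
  ds <- fixed_diff_geno(n_per_pop = 8, n_loci = 6)
  r <- admixture_mcmc(ds, 2, burn_in = 1000, iterations = 4000, seed = 2)
  own <- ifelse(ds$individuals$population == "pop1",
                r$Q[, which.max(r$Q[1, ])], r$Q[, which.min(r$Q[1, ])])
  expect_gt(mean(own), 0.99)
})

test_that("duplicated individuals get near-identical memberships", {
  ds <- random_geno(seed = 8, n_per_pop = c(5, 5), miss = 0)
  n <- nrow(ds$individuals)
  arr <- ds$alleles[rep(seq_len(n), each = 2), , , drop = FALSE]
  ind <- ds$individuals[rep(seq_len(n), each = 2), ]
  ind$individual <- sprintf("d%02d", seq_len(2 * n))
  dup <- microsat_data(arr, ind, ds$loci)
  r <- admixture_mcmc(dup, 2, burn_in = 1500, iterations = 6000, seed = 3)
  gap <- abs(r$Q[seq(1, 2 * n, 2), 1] - r$Q[seq(2, 2 * n, 2), 1])
  expect_lt(max(gap), 0.06)
})

test_that("Evanno table reproduces hand arithmetic of the formula", {
  mk_run <- function(k, lnp) structure(list(K = k, lnP = lnp),
                                       class = "ssr_structure")
  means <- c(-100, -50, -45, -44)
  runs <- unlist(lapply(1:4, function(k)
    lapply(means[k] + c(-1, 0, 1), function(v) mk_run(k, v))),
    recursive = FALSE)
  dk <- evanno_deltak(runs)
  expect_equal(dk$sd_lnp, rep(1, 4))
  expect_equal(dk$lnp1, c(NA, 50, 5, 1))
  expect_equal(dk$lnp2, c(NA, 45, 4, NA))
  expect_equal(dk$delta_k, c(NA, 45, 4, NA))

  flat <- unlist(lapply(1:3, function(k)
    lapply(c(-10, -10), function(v) mk_run(k, v))), recursive = FALSE)
  dkf <- evanno_deltak(flat)
  expect_equal(dkf$delta_k[2], 0)

  expect_error(evanno_deltak(list(mk_run(1, -5), mk_run(1, -6),
                                  mk_run(2, -4), mk_run(2, -5))),
               "length >= 3")
  expect_error(evanno_deltak(list(mk_run(1, -5), mk_run(2, -4),
                                  mk_run(4, -3))), "missing K")
})

test_that("run alignment undoes label switching and averages", {
  set.seed(7)
  q <- matrix(rgamma(30 * 3, 1), 30, 3)
  q <- q / rowSums(q)
  ind <- tibble::tibble(individual = sprintf("i%02d", 1:30),
                        population = "p", species = "s")
  mk <- function(Q) {
    colnames(Q) <- paste0("cluster", 1:3)
    structure(list(K = 3, Q = Q,
                   q_table = dplyr::bind_cols(ind, tibble::as_tibble(Q))),
              class = "ssr_structure")
  }
  perm <- c(3, 1, 2)
  al <- align_runs(list(mk(q), mk(q[, perm])))
  expect_equal(al$permutations[[1]], 1:3)
  expect_equal(al$aligned[[2]], unname(q), ignore_attr = TRUE)
  expect_equal(al$mean_q, q, ignore_attr = TRUE)

  # noisy replicates: the aligned mean is closer to truth than any run
  noisy <- lapply(1:3, function(i) {
    qn <- q + matrix(runif(90, 0, 0.25), 30, 3)
    qn <- qn / rowSums(qn)
    mk(qn[, sample(3)])
  })
  aln <- align_runs(c(list(mk(q)), noisy))
  frob <- function(m) sqrt(sum((m - q)^2))
  d_mean <- frob(aln$mean_q)
  d_each <- vapply(aln$aligned[-1], frob, numeric(1))
  expect_true(d_mean < min(d_each))

  bad <- mk(q)
  bad$q_table$individual <- rev(bad$q_table$individual)
  expect_error(align_runs(list(mk(q), bad)), "individual ordering")
})

test_that("DAPC separates planted groups and respects preconditions", {
  set.seed(17)
  fixed <- fixed_diff_geno(n_per_pop = 10, n_loci = 5)
  noise <- array(sample(1:4, 20 * 3 * 2, TRUE), c(20, 3, 2))
  arr <- array(NA_integer_, c(20, 8, 2))
  arr[, 1:5, ] <- fixed$alleles
  arr[, 6:8, ] <- noise
  arr[2, , ] <- arr[1, , ]  # duplicate of individual 1
  ds <- microsat_data(arr, fixed$individuals)
  fit <- dapc_fit(ds, groups = "species", n_pcs = 2)
  expect_equal(mean(fit$assigned == fit$groups), 1)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_lte(ncol(fit$ld_scores), 1)  # 2 groups -> 1 discriminant axis

  # duplicate individuals land on identical coordinates
  d <- tidy(fit)
  expect_equal(d$LD1[1], d$LD1[2])

  one <- random_geno(seed = 4, n_per_pop = c(1, 5), miss = 0)
  expect_error(dapc_fit(one, groups = "population"), "single individual")
})

test_that("random labels give memberships near the group priors", {
  set.seed(10)
  ds <- random_geno(seed = 10, n_per_pop = c(20, 20), miss = 0, n_loci = 8)
  # shuffle species labels so groups carry no signal
  ds$individuals$species <- sample(ds$individuals$species)
  ds$individuals$population <- ds$individuals$species
  fit <- dapc_fit(ds, groups = "species", n_pcs = 2)
  prior <- mean(ds$individuals$species == "spA")
  expect_lt(abs(mean(fit$membership[, "spA"]) - prior), 0.2)
})
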