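# small in-code fixtures shared across test files

# hand-built diploid dataset: n individuals per population, explicit
# allele arrays
toy_geno <- function(allele_list, pops, species = NULL) {
  # allele_list: list of n x 2 matrices, one per locus
  n <- nrow(allele_list[[1]])
  arr <- array(NA_integer_, c(n, length(allele_list), 2))
  for (l in seq_along(allele_list)) arr[, l, ] <- allele_list[[l]]
  species <- species %||% pops
  microsat_data(arr, tibble::tibble(
    individual = sprintf("i%02d", seq_len(n)),
    population = pops, species = species))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small dataset with missing copies, for round-trip tests
random_geno <- function(seed = 1, n_per_pop = c(3, 4, 2), n_loci = 4,
                        miss = 0.1) {
  set.seed(seed)
  n <- sum(n_per_pop)
  arr <- array(sample(1:8, n * n_loci * 2, replace = TRUE),
               c(n, n_loci, 2))
  arr[runif(length(arr)) < miss] <- NA_integer_
  # avoid a locus entirely missing
  arr[1, , ] <- 5L
  pops <- rep(sprintf("P%d", seq_along(n_per_pop)), n_per_pop)
  sp <- ifelse(pops == "P1", "spA", "spB")
  microsat_data(arr, tibble::tibble(
    individual = sprintf("i%02d", seq_len(n)),
    population = pops, species = sp))
}

# two populations fixed for different alleles at every locus
fixed_diff_geno <- function(n_per_pop = 8, n_loci = 6) {
  al <- lapply(seq_len(n_loci), function(l)
    rbind(matrix(100L, n_per_pop, 2), matrix(110L, n_per_pop, 2)))
  toy_geno(al, rep(c("pop1", "pop2"), each = n_per_pop),
           rep(c("spA", "spB"), each = n_per_pop))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
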