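# Data model and file I/O for diploid microsatellite genotypes.

#' Diploid microsatellite genotype container
#'
#' Bundles an integer allele array (individuals x loci x 2 gene copies,
#' allele states in repeat-count units, `NA` = missing) with the
#' individual-level grouping table (individual, population, species).
#' Every individual belongs to exactly one population and every
#' population to exactly one species.
#'
#' @param alleles integer array of dimension `c(n, L, 2)`; positive
#'   allele states, `NA` for missing gene copies.
#' @param individuals data frame with columns `individual`, `population`,
#'   `species` (one row per individual, same order as `alleles` rows).
#' @param loci character vector of `L` locus names.
#' @return An object of class `ssr_geno`.
#' @export
microsat_data <- function(alleles, individuals, loci = NULL) {
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("`alleles` must be an n x L x 2 integer array", call. = FALSE)
  individuals <- tibble::as_tibble(individuals)
  need <- c("individual", "population", "species")
  if (!all(need %in% names(individuals)))
    stop("`individuals` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(individuals) != dim(alleles)[1])
    stop("row count of `individuals` does not match `alleles`", call. = FALSE)
  loci <- loci %||% dimnames(alleles)[[2]] %||%
    sprintf("L%02d", seq_len(dim(alleles)[2]))
  if (anyDuplicated(loci)) stop("duplicated locus name", call. = FALSE)
  if (length(loci) != dim(alleles)[2])
    stop("`loci` length does not match `alleles`", call. = FALSE)
  storage.mode(alleles) <- "integer"
  if (any(alleles[!is.na(alleles)] <= 0L))
    stop("all non-missing allele states must be positive integers",
         call. = FALSE)
  # population -> species map must be a function
  map <- unique(individuals[, c("population", "species")])
  if (anyDuplicated(map$population))
    stop("a population maps to more than one species", call. = FALSE)
  dimnames(alleles) <- list(individuals$individual, loci, c("a1", "a2"))
  structure(list(alleles = alleles, individuals = individuals, loci = loci),
            class = "ssr_geno")
}

#' @export
print.ssr_geno <- function(x, ...) {
  cat("<ssr_geno> ", nrow(x$individuals), " diploid individuals, ",
      length(x$loci), " loci\n", sep = "")
  tab <- dplyr::count(x$individuals, .data$species, .data$population)
  print(tab, n = Inf)
  invisible(x)
}

#' @export
dim.ssr_geno <- function(x) c(nrow(x$individuals), length(x$loci))

#' Long-format view of a genotype container
#'
#' @param x an `ssr_geno` object.
#' @param ... ignored.
#' @return Tibble with one row per gene copy:
#'   individual, population, species, locus, copy, allele.
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.ssr_geno <- function(x, ...) {
  n <- nrow(x$individuals); L <- length(x$loci)
  tibble::tibble(
    individual = rep(x$individuals$individual, times = 2L * L),
    population = rep(x$individuals$population, times = 2L * L),
    species    = rep(x$individuals$species,   times = 2L * L),
    locus      = rep(rep(x$loci, each = n), times = 2L),
    copy       = rep(1:2, each = n * L),
    allele     = as.vector(x$alleles))
}

# copies x loci matrix (rows 2i-1, 2i = copies of individual i)
copies_matrix <- function(ds) {
  n <- nrow(ds$individuals); L <- length(ds$loci)
  m <- matrix(NA_integer_, 2L * n, L, dimnames = list(NULL, ds$loci))
  m[seq(1, 2 * n, by = 2), ] <- ds$alleles[, , 1]
  m[seq(2, 2 * n, by = 2), ] <- ds$alleles[, , 2]
  m
}

#' Read a grouping table (individual, population, species)
#'
#' @param path CSV file with columns individual, population, species.
#' @return tibble
#' @export
read_grouping <- function(path) {
  g <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("individual", "population", "species")
  if (!all(need %in% names(g)))
    stop("grouping file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  g
}

#' Read a GenePop file
#'
#' Standard GenePop dialect: title line, one locus name per line (or one
#' comma-separated line), `Pop` markers, and diploid genotypes coded with
#' 3 digits per allele (`000` = missing). Species labels come from an
#' optional sidecar grouping table; without one, each population is
#' treated as its own species.
#'
#' @param path GenePop text file.
#' @param grouping optional grouping tibble or CSV path
#'   (see [read_grouping()]).
#' @param offset integer subtracted from every non-missing allele state
#'   on import (per-locus vector or scalar), for converting fragment
#'   lengths to repeat counts. Default 0.
#' @return [microsat_data()] object.
#' @export
read_genepop <- function(path, grouping = NULL, offset = 0L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GenePop file: too short", call. = FALSE)
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no 'Pop' line found", call. = FALSE)
  loc_lines <- lines[2:(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci))
    stop("duplicated locus name: ", loci[duplicated(loci)][1], call. = FALSE)
  L <- length(loci)
  offset <- rep_len(as.integer(offset), L)

  ids <- character(); pops <- character(); rows <- list()
  pop_bounds <- c(pop_idx, length(lines) + 1L)
  for (p in seq_along(pop_idx)) {
    block <- lines[(pop_bounds[p] + 1L):(pop_bounds[p + 1L] - 1L)]
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2)
        stop("malformed genotype line (no comma): ", ln, call. = FALSE)
      id <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
      if (length(genos) != L)
        stop("individual '", id, "': expected ", L, " genotypes, got ",
             length(genos), call. = FALSE)
      if (any(nchar(genos) != 6L))
        stop("individual '", id, "': genotype not 6 digits wide at locus ",
             loci[which(nchar(genos) != 6L)[1]], call. = FALSE)
      a1 <- as.integer(substr(genos, 1, 3))
      a2 <- as.integer(substr(genos, 4, 6))
      a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
      ids <- c(ids, id); pops <- c(pops, sprintf("Pop%d", p))
      rows[[length(rows) + 1L]] <- cbind(a1 - ifelse(is.na(a1), 0L, offset),
                                         a2 - ifelse(is.na(a2), 0L, offset))
    }
  }
  n <- length(ids)
  alleles <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) alleles[i, , ] <- rows[[i]]
  if (!is.null(grouping)) {
    if (is.character(grouping)) grouping <- read_grouping(grouping)
    m <- match(ids, grouping$individual)
    if (anyNA(m)) stop("individual missing from grouping: ",
                       ids[which(is.na(m))[1]], call. = FALSE)
    ind <- tibble::tibble(individual = ids,
                          population = grouping$population[m],
                          species = grouping$species[m])
  } else {
    ind <- tibble::tibble(individual = ids, population = pops, species = pops)
  }
  microsat_data(alleles, ind, loci)
}

#' Write a GenePop file
#'
#' @param ds [microsat_data()] object; all allele states must be < 1000.
#' @param path output file.
#' @param title first (title) line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "ssrdiverge export") {
  assert_ssr_geno(ds)
  if (nrow(ds$individuals) == 0) stop("empty dataset", call. = FALSE)
  if (any(ds$alleles >= 1000L, na.rm = TRUE))
    stop("allele state >= 1000 cannot be 3-digit coded", call. = FALSE)
  enc <- function(a) sprintf("%03d", ifelse(is.na(a), 0L, a))
  out <- c(title, ds$loci)
  for (p in unique(ds$individuals$population)) {
    out <- c(out, "Pop")
    for (i in which(ds$individuals$population == p)) {
      g <- paste0(enc(ds$alleles[i, , 1]), enc(ds$alleles[i, , 2]))
      out <- c(out, paste0(ds$individuals$individual[i], " ,  ",
                           paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a STRUCTURE-format genotype matrix
#'
#' Whitespace-delimited table: header of locus names, then per
#' individual either two rows (one per gene copy,
#' `one_row_per_copy = TRUE`) or one row with two adjacent columns per
#' locus. First two columns are individual and population labels; -9
#' marks missing.
#'
#' @inheritParams read_genepop
#' @param one_row_per_copy logical; two-row-per-individual layout.
#' @return [microsat_data()] object.
#' @export
read_structure_table <- function(path, one_row_per_copy = TRUE,
                                 grouping = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  L <- length(loci)
  parse_row <- function(x) {
    if (length(x) != 2 + (if (one_row_per_copy) L else 2 * L))
      stop("row with wrong field count: ", paste(x, collapse = " "),
           call. = FALSE)
    v <- as.integer(x[-(1:2)])
    v[v == -9L] <- NA_integer_
    v
  }
  if (one_row_per_copy) {
    if (length(body) %% 2L != 0L)
      stop("odd row count in two-row-per-individual mode", call. = FALSE)
    n <- length(body) / 2L
    ids <- popchr <- character(n)
    alleles <- array(NA_integer_, c(n, L, 2))
    for (i in seq_len(n)) {
      r1 <- body[[2 * i - 1]]; r2 <- body[[2 * i]]
      if (r1[1] != r2[1])
        stop("row pair with mismatched individual id: ", r1[1], call. = FALSE)
      ids[i] <- r1[1]; popchr[i] <- r1[2]
      alleles[i, , 1] <- parse_row(r1)
      alleles[i, , 2] <- parse_row(r2)
    }
  } else {
    n <- length(body)
    ids <- popchr <- character(n)
    alleles <- array(NA_integer_, c(n, L, 2))
    for (i in seq_len(n)) {
      v <- parse_row(body[[i]])
      ids[i] <- body[[i]][1]; popchr[i] <- body[[i]][2]
      alleles[i, , 1] <- v[seq(1, 2 * L, by = 2)]
      alleles[i, , 2] <- v[seq(2, 2 * L, by = 2)]
    }
  }
  if (!is.null(grouping)) {
    if (is.character(grouping)) grouping <- read_grouping(grouping)
    m <- match(ids, grouping$individual)
    if (anyNA(m)) stop("individual missing from grouping: ",
                       ids[which(is.na(m))[1]], call. = FALSE)
    ind <- tibble::tibble(individual = ids,
                          population = grouping$population[m],
                          species = grouping$species[m])
  } else {
    ind <- tibble::tibble(individual = ids, population = popchr,
                          species = popchr)
  }
  microsat_data(alleles, ind, loci)
}

#' Write a STRUCTURE-format genotype matrix
#'
#' @inheritParams write_genepop
#' @param one_row_per_copy logical; two-row-per-individual layout.
#' @export
write_structure_table <- function(ds, path, one_row_per_copy = TRUE) {
  assert_ssr_geno(ds)
  if (nrow(ds$individuals) == 0) stop("empty dataset", call. = FALSE)
  enc <- function(a) ifelse(is.na(a), -9L, a)
  out <- paste(ds$loci, collapse = " ")
  for (i in seq_len(nrow(ds$individuals))) {
    id <- ds$individuals$individual[i]; p <- ds$individuals$population[i]
    if (one_row_per_copy) {
      out <- c(out,
               paste(c(id, p, enc(ds$alleles[i, , 1])), collapse = " "),
               paste(c(id, p, enc(ds$alleles[i, , 2])), collapse = " "))
    } else {
      g <- as.vector(rbind(enc(ds$alleles[i, , 1]), enc(ds$alleles[i, , 2])))
      out <- c(out, paste(c(id, p, g), collapse = " "))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Per-group allele frequencies
#'
#' Counts exclude missing gene copies. A locus with no scored copy in a
#' group is kept as a flagged row (`n_copies = 0`, `freq = NA`) with a
#' warning rather than silently dropped.
#'
#' @param ds [microsat_data()] object.
#' @param by grouping level, `"population"` or `"species"`.
#' @return tibble: group, locus, allele, count, freq, n_copies.
#' @export
allele_frequencies <- function(ds, by = c("population", "species")) {
  assert_ssr_geno(ds)
  by <- match.arg(by)
  long <- as_tibble(ds)
  long$group <- long[[by]]
  counted <- long |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$group, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::mutate(n_copies = sum(.data$count),
                  freq = .data$count / .data$n_copies) |>
    dplyr::ungroup()
  full <- tidyr::expand_grid(group = unique(long$group), locus = ds$loci)
  missing <- dplyr::anti_join(full, counted, by = c("group", "locus"))
  if (nrow(missing) > 0) {
    warning("locus entirely missing in a group: ",
            paste(paste0(missing$group, "/", missing$locus), collapse = ", "),
            call. = FALSE)
    counted <- dplyr::bind_rows(
      counted,
      dplyr::mutate(missing, allele = NA_integer_, count = 0L,
                    n_copies = 0L, freq = NA_real_))
  }
  dplyr::arrange(counted, .data$group, .data$locus, .data$allele)
}

# per-population allele count matrices (pops x alleles), one per locus
count_matrices <- function(ds) {
  cm <- copies_matrix(ds)
  pops <- unique(ds$individuals$population)
  pop_of_copy <- rep(ds$individuals$population, each = 2L)
  lapply(seq_along(ds$loci), function(l) {
    al <- cm[, l]
    keep <- !is.na(al)
    lv <- sort(unique(al[keep]))
    t(vapply(pops, function(p) {
      tabulate(match(al[keep & pop_of_copy == p], lv), length(lv))
    }, integer(length(lv))))
  })
}
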