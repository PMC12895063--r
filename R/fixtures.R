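#' Specification for a synthetic EIGENSTRAT fixture
#'
#' Describes a dataset the generator can produce deterministically:
#' genotypes are drawn as binomial(2, f) with per-SNP allele frequencies f
#' from a Beta distribution, then masked to missing with a per-SNP rate
#' drawn uniformly from `missing_range`, multiplied by a per-individual
#' inflation factor drawn uniformly from `ind_missing_inflation` (clamped
#' to 1). No linkage disequilibrium is simulated. Sex-chromosome rows are
#' drawn from the same model, so biologically impossible calls (female Y,
#' male X heterozygote) occur and exercise sanitization.
#'
#' @param n_ind Number of individuals.
#' @param snp_counts Named integer vector: SNPs per chromosome code
#'   (include the sex codes 23/24 to get X/Y rows).
#' @param freq_beta Shape parameters of the Beta allele-frequency prior.
#' @param missing_range Range of per-SNP missing rates.
#' @param ind_missing_inflation Range of per-individual multipliers on the
#'   SNP missing rate.
#' @param sex_props Proportions of M/F/U individuals (must sum to 1).
#' @param populations Named integer vector: individuals per population
#'   label (must sum to `n_ind`).
#' @param seed Integer seed; output is byte-identical given the same spec.
#' @return An object of class `es_fixture_spec`.
#' @export
fixture_spec <- function(n_ind = 20L,
                         snp_counts = c(`1` = 60L, `2` = 40L, `23` = 10L, `24` = 10L),
                         freq_beta = c(0.8, 0.8),
                         missing_range = c(0, 0.3),
                         ind_missing_inflation = c(0.5, 2),
                         sex_props = c(M = 0.4, F = 0.4, U = 0.2),
                         populations = NULL,
                         seed = 1L) {
  n_ind <- as.integer(n_ind)
  if (is.na(n_ind) || n_ind < 1L) stop_es("fixture needs at least one individual")
  if (any(snp_counts < 0L) || sum(snp_counts) < 1L)
    stop_es("fixture needs at least one SNP")
  if (abs(sum(sex_props) - 1) > 1e-8) stop_es("sex proportions must sum to 1")
  if (any(missing_range < 0) || any(missing_range > 1))
    stop_es("missing rates must lie in [0, 1]")
  if (is.null(populations)) {
    half <- n_ind %/% 2L
    populations <- c(Pop1 = half, Pop2 = n_ind - half)
    if (n_ind == 1L) populations <- c(Pop1 = 1L)
  }
  if (sum(populations) != n_ind)
    stop_es("population sizes must sum to n_ind")
  structure(list(n_ind = n_ind, snp_counts = snp_counts,
                 freq_beta = freq_beta, missing_range = missing_range,
                 ind_missing_inflation = ind_missing_inflation,
                 sex_props = sex_props, populations = populations,
                 seed = as.integer(seed)),
            class = "es_fixture_spec")
}

#' Read a fixture specification from a flat key-value file
#'
#' Lines of `key = value`; vector values are comma-separated, and
#' `snp_counts`/`populations` use `name:count` pairs.
#'
#' @param path Path to the spec file.
#' @return An `es_fixture_spec`.
#' @export
read_fixture_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) != 2L) stop_es("fixture spec parse error: ", paste(p, collapse = "="))
    key <- trimws(p[1]); val <- trimws(p[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (all(grepl(":", parts, fixed = TRUE))) {
      pr <- strsplit(parts, ":", fixed = TRUE)
      v <- stats::setNames(as.numeric(vapply(pr, `[`, "", 2)),
                           vapply(pr, `[`, "", 1))
    } else {
      v <- suppressWarnings(as.numeric(parts))
      if (anyNA(v)) v <- parts
    }
    args[[key]] <- v
  }
  do.call(fixture_spec, args)
}

#' Generate a synthetic EIGENSTRAT dataset with truth tables
#'
#' Writes a valid `.geno`/`.snp`/`.ind` triple plus machine-readable truth
#' files computed by direct enumeration over the simulated matrix (simple
#' per-element loops independent of the streaming readers, statistics and
#' filter code): `<prefix>.truth_snp.tsv` (per-SNP frequency, MAF, missing
#' rate with sex-aware denominators) and `<prefix>.truth_ind.tsv`
#' (per-individual missing rate).
#'
#' @param spec An `es_fixture_spec`.
#' @param out_prefix Output prefix, or `NULL` to keep everything in memory.
#' @return List with `values`, `snp`, `ind`, `truth_snp`, `truth_ind`
#'   (invisibly when written to disk).
#' @export
generate_fixture <- function(spec, out_prefix = NULL) {
  stopifnot(inherits(spec, "es_fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n_ind <- spec$n_ind
  n_snp <- sum(spec$snp_counts)

  sex <- sample(names(spec$sex_props), n_ind, replace = TRUE,
                prob = spec$sex_props)
  ind <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_ind)),
    sex = sex,
    population = rep(names(spec$populations), times = spec$populations),
    stringsAsFactors = FALSE)

  chrom <- rep(as.integer(names(spec$snp_counts)), times = spec$snp_counts)
  pos <- unlist(lapply(spec$snp_counts, function(k)
    sort(sample.int(10000000L, k))), use.names = FALSE)
  alleles <- t(vapply(seq_len(n_snp),
                      function(i) sample(c("A", "C", "G", "T"), 2L), character(2)))
  snp <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(n_snp)),
    chrom = chrom,
    genetic_pos = round(pos * 1e-8, 10),
    physical_pos = as.numeric(pos),
    allele1 = alleles[, 1], allele2 = alleles[, 2],
    stringsAsFactors = FALSE)

  f <- rbeta(n_snp, spec$freq_beta[1], spec$freq_beta[2])
  values <- matrix(rbinom(n_snp * n_ind, 2L, rep(f, n_ind)),
                   nrow = n_snp, ncol = n_ind)
  p_snp <- runif(n_snp, spec$missing_range[1], spec$missing_range[2])
  infl <- runif(n_ind, spec$ind_missing_inflation[1], spec$ind_missing_inflation[2])
  p_miss <- pmin(outer(p_snp, infl), 1)
  values[matrix(runif(n_snp * n_ind), n_snp) < p_miss] <- 9L
  storage.mode(values) <- "integer"

  truth <- enumerate_truth(values, chrom, sex, sex_chr = c(23L, 24L))
  truth$snp <- cbind(snp_id = snp$snp_id, truth$snp)
  truth$ind <- cbind(sample_id = ind$sample_id, truth$ind)

  result <- list(values = values, snp = snp, ind = ind,
                 truth_snp = truth$snp, truth_ind = truth$ind)
  if (!is.null(out_prefix)) {
    es_write(values, snp, ind, out_prefix, "TEXT")
    write.table(truth$snp, paste0(out_prefix, ".truth_snp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth$ind, paste0(out_prefix, ".truth_ind.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(result))
  }
  result
}

# Direct enumeration of the per-SNP and per-individual truth statistics.
# Deliberately written as plain elementwise loops so it shares no code with
# the streaming statistics it is used to check.
enumerate_truth <- function(values, chrom, sex, sex_chr = c(23L, 24L)) {
  n_snp <- nrow(values); n_ind <- ncol(values)
  freq <- maf <- miss <- numeric(n_snp)
  n_obs <- n_cons <- integer(n_snp)
  for (i in seq_len(n_snp)) {
    is_y <- chrom[i] == sex_chr[2]
    cons <- 0L; obs <- 0L; refc <- 0
    for (j in seq_len(n_ind)) {
      if (is_y && sex[j] != "M") next
      cons <- cons + 1L
      g <- values[i, j]
      if (g != 9L) {
        obs <- obs + 1L
        refc <- refc + g
      }
    }
    n_cons[i] <- cons; n_obs[i] <- obs
    freq[i] <- if (obs > 0L) refc / (2 * obs) else NA_real_
    maf[i] <- if (obs > 0L) min(freq[i], 1 - freq[i]) else NA_real_
    miss[i] <- if (cons > 0L) (cons - obs) / cons else NA_real_
  }
  imiss <- icons <- integer(n_ind)
  for (j in seq_len(n_ind)) {
    for (i in seq_len(n_snp)) {
      if (chrom[i] == sex_chr[2] && sex[j] != "M") next
      icons[j] <- icons[j] + 1L
      if (values[i, j] == 9L) imiss[j] <- imiss[j] + 1L
    }
  }
  list(snp = data.frame(n_considered = n_cons, n_obs = n_obs, freq = freq,
                        maf = maf, missing_rate = miss),
       ind = data.frame(n_considered = icons, n_missing = imiss,
                        missing_rate = ifelse(icons > 0, imiss / icons, NA_real_)))
}

#' The worked micro dataset
#'
#' A fixed 6-individual (two populations; sexes M, M, F, F, U, M) by
#' 10-SNP dataset (six autosomal, two X-coded, two Y-coded rows) with
#' hand-placed heterozygotes, missing entries, a monomorphic SNP, an
#' all-missing SNP, female Y calls and male X heterozygotes, so that every
#' filter and transform branch is reachable. Used in documentation and
#' tests.
#'
#' @return List with `values` (10 x 6 integer matrix), `snp`, `ind`.
#' @export
micro_dataset <- function() {
  ind <- data.frame(
    sample_id = paste0("S", 1:6),
    sex = c("M", "M", "F", "F", "U", "M"),
    population = c("P1", "P1", "P1", "P2", "P2", "P2"),
    stringsAsFactors = FALSE)
  snp <- data.frame(
    snp_id = c(paste0("rs", 1:6), "rsX1", "rsX2", "rsY1", "rsY2"),
    chrom = c(rep(1L, 6), 23L, 23L, 24L, 24L),
    genetic_pos = c(0.001, 0.002, 0.003, 0.004, 0.005, 0.006,
                    0.001, 0.002, 0.001, 0.002),
    physical_pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5, 1e5, 2e5, 1e5, 2e5),
    allele1 = c("A", "C", "G", "T", "A", "C", "G", "A", "C", "T"),
    allele2 = c("G", "T", "A", "C", "G", "T", "A", "G", "T", "A"),
    stringsAsFactors = FALSE)
  geno_lines <- c(
    "012129",  # rs1: het, missing
    "000000",  # rs2: monomorphic
    "221122",  # rs3: maf exactly 1/6, the inclusive min-maf boundary case
    "999999",  # rs4: all missing
    "111111",  # rs5: all heterozygous
    "010209",  # rs6
    "102011",  # rsX1: male X heterozygotes (columns 1 and 6)
    "220912",  # rsX2
    "202092",  # rsY1: non-male Y calls (columns 3 and 4)
    "909199")  # rsY2
  values <- matrix(utf8ToInt(paste(geno_lines, collapse = "")) - 48L,
                   nrow = 10L, ncol = 6L, byrow = TRUE)
  list(values = values, snp = snp, ind = ind)
}

#' Write the micro dataset to disk
#' @param out_prefix Output prefix.
#' @return `out_prefix`, invisibly.
#' @export
write_micro_dataset <- function(out_prefix) {
  m <- micro_dataset()
  es_write(m$values, m$snp, m$ind, out_prefix, "TEXT")
}
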