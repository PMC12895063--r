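# Naive whole-matrix reference implementation, kept deliberately simple and
# independent of the streaming code paths: plain loops and subscripting on
# the full genotype matrix, applied in the documented operation order.

ref_snp_stats <- function(values, chrom, sex, sex_chr = c(23L, 24L),
                          ignore_sex = FALSE, ignore_unknown = FALSE) {
  n <- nrow(values)
  out <- data.frame(n_considered = integer(n), n_obs = integer(n),
                    freq = NA_real_, maf = NA_real_, missing_rate = NA_real_)
  for (i in seq_len(n)) {
    cols <- seq_along(sex)
    if (!ignore_sex) {
      if (chrom[i] == sex_chr[2]) cols <- which(sex == "M")
      else if (chrom[i] == sex_chr[1] && ignore_unknown) cols <- which(sex != "U")
    }
    g <- values[i, cols]
    obs <- g[g != 9L]
    out$n_considered[i] <- length(cols)
    out$n_obs[i] <- length(obs)
    if (length(obs)) {
      f <- sum(obs) / (2 * length(obs))
      out$freq[i] <- f
      out$maf[i] <- min(f, 1 - f)
    }
    if (length(cols))
      out$missing_rate[i] <- (length(cols) - length(obs)) / length(cols)
  }
  out
}

ref_ind_missing <- function(values, chrom, sex, sex_chr = c(23L, 24L),
                            ignore_sex = FALSE, ignore_unknown = FALSE) {
  nj <- length(sex)
  n_considered <- n_missing <- integer(nj)
  for (j in seq_len(nj)) {
    for (i in seq_len(nrow(values))) {
      if (!ignore_sex) {
        if (chrom[i] == sex_chr[2] && sex[j] != "M") next
        if (ignore_unknown && chrom[i] == sex_chr[1] && sex[j] == "U") next
      }
      n_considered[j] <- n_considered[j] + 1L
      if (values[i, j] == 9L) n_missing[j] <- n_missing[j] + 1L
    }
  }
  data.frame(n_considered = n_considered, n_missing = n_missing,
             missing_rate = ifelse(n_considered > 0,
                                   n_missing / n_considered, NA_real_))
}

# Full reference pipeline on in-memory data. opts is a list with any of:
# polarize_table (named ancestral alleles), polarize_sample (sample id),
# seed (haploidise), keep_pop/remove_pop/keep_indv/remove_indv (vectors),
# sex_chr_missing, keep_snps/remove_snps (vectors),
# regions_keep/regions_remove (data.frame chrom,start,end),
# chrom_keep/chrom_remove (integer vectors), geno, min_maf, max_maf.
ref_pipeline <- function(values, snp, ind, opts = list(), sex_chr = c(23L, 24L)) {
  o <- function(nm) opts[[nm]]

  # (ii) polarization
  if (!is.null(o("polarize_table")) || !is.null(o("polarize_sample"))) {
    n <- nrow(values)
    anc <- rep(NA_character_, n)
    if (!is.null(o("polarize_table"))) {
      anc <- unname(o("polarize_table")[snp$snp_id])
    } else {
      j <- match(o("polarize_sample"), ind$sample_id)
      for (i in seq_len(n)) {
        if (values[i, j] == 2L) anc[i] <- snp$allele1[i]
        if (values[i, j] == 0L) anc[i] <- snp$allele2[i]
      }
    }
    keep <- logical(n)
    for (i in seq_len(n)) {
      if (is.na(anc[i])) next
      if (toupper(anc[i]) == toupper(snp$allele1[i])) keep[i] <- TRUE
      else if (toupper(anc[i]) == toupper(snp$allele2[i])) {
        keep[i] <- TRUE
        tmp <- snp$allele1[i]; snp$allele1[i] <- snp$allele2[i]; snp$allele2[i] <- tmp
        for (j in seq_len(ncol(values)))
          if (values[i, j] != 9L) values[i, j] <- 2L - values[i, j]
      }
    }
    values <- values[keep, , drop = FALSE]
    snp <- snp[keep, , drop = FALSE]
  }

  # (iii) haploidization (same keyed draws as the package: one RNG stream
  # per absolute input row, one uniform per column)
  if (!is.null(o("seed"))) {
    seeds <- haploid_row_seeds(o("seed"), attr(values, "n_input_rows") %||% nrow(values))
    rows_in <- attr(values, "input_row") %||% seq_len(nrow(values))
    for (i in seq_len(nrow(values))) {
      set.seed(seeds[rows_in[i]])
      u <- runif(ncol(values))
      for (j in seq_len(ncol(values)))
        if (values[i, j] == 1L) values[i, j] <- if (u[j] > 0.5) 2L else 0L
    }
  }

  # (iv) individual/population filtering: population level then individual
  mask <- rep(TRUE, nrow(ind))
  if (!is.null(o("keep_pop"))) mask <- mask & ind$population %in% o("keep_pop")
  if (!is.null(o("remove_pop"))) mask <- mask & !(ind$population %in% o("remove_pop"))
  if (!is.null(o("keep_indv"))) mask <- mask & ind$sample_id %in% o("keep_indv")
  if (!is.null(o("remove_indv"))) mask <- mask & !(ind$sample_id %in% o("remove_indv"))
  values <- values[, mask, drop = FALSE]
  ind <- ind[mask, , drop = FALSE]

  # (v) sex-chromosome sanitization
  if (isTRUE(o("sex_chr_missing"))) {
    for (i in which(snp$chrom == sex_chr[2]))
      for (j in which(ind$sex != "M")) values[i, j] <- 9L
    for (i in which(snp$chrom == sex_chr[1]))
      for (j in which(ind$sex == "M"))
        if (values[i, j] == 1L) values[i, j] <- 9L
  }

  # (vi) SNP-ID selection, (vii) region/chromosome
  keep <- rep(TRUE, nrow(snp))
  if (!is.null(o("keep_snps"))) keep <- keep & snp$snp_id %in% o("keep_snps")
  if (!is.null(o("remove_snps"))) keep <- keep & !(snp$snp_id %in% o("remove_snps"))
  in_regions <- function(rg) {
    hit <- logical(nrow(snp))
    for (i in seq_len(nrow(snp)))
      for (k in seq_len(nrow(rg)))
        if (snp$chrom[i] == rg$chrom[k] &&
            snp$physical_pos[i] >= rg$start[k] &&
            snp$physical_pos[i] <= rg$end[k]) hit[i] <- TRUE
    hit
  }
  if (!is.null(o("regions_keep"))) keep <- keep & in_regions(o("regions_keep"))
  if (!is.null(o("regions_remove"))) keep <- keep & !in_regions(o("regions_remove"))
  if (!is.null(o("chrom_keep"))) keep <- keep & snp$chrom %in% o("chrom_keep")
  if (!is.null(o("chrom_remove"))) keep <- keep & !(snp$chrom %in% o("chrom_remove"))
  values <- values[keep, , drop = FALSE]
  snp <- snp[keep, , drop = FALSE]

  # (viii) statistics on post-selection data
  st <- ref_snp_stats(values, snp$chrom, ind$sex, sex_chr,
                      isTRUE(o("ignore_sex")), isTRUE(o("ignore_unknown")))
  im <- ref_ind_missing(values, snp$chrom, ind$sex, sex_chr,
                        isTRUE(o("ignore_sex")), isTRUE(o("ignore_unknown")))

  # (ix) geno then MAF filters
  keep <- rep(TRUE, nrow(snp))
  if (!is.null(o("geno")))
    keep <- keep & (is.na(st$missing_rate) | st$missing_rate <= o("geno"))
  maf0 <- ifelse(is.na(st$maf), 0, st$maf)
  if (!is.null(o("min_maf"))) keep <- keep & maf0 >= o("min_maf")
  if (!is.null(o("max_maf"))) keep <- keep & maf0 <= o("max_maf")
  list(values = values[keep, , drop = FALSE], snp = snp[keep, , drop = FALSE],
       ind = ind, frq = st, imiss = im)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write an in-memory triple to a temporary prefix and return the prefix.
write_tmp_dataset <- function(values, snp, ind, encoding = "TEXT",
                              prefix = tempfile("es")) {
  es_write(values, snp, ind, prefix, encoding)
  prefix
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

random_fixture <- function(seed, max_ind = 50L, max_snp = 500L) {
  set.seed(seed)
  n_ind <- sample(2:max_ind, 1)
  counts <- c(sample.int(max(1L, max_snp %/% 3), 2), sample.int(20, 2))
  names(counts) <- c("1", "2", "23", "24")
  generate_fixture(fixture_spec(
    n_ind = n_ind, snp_counts = counts,
    missing_range = c(0, runif(1, 0, 0.4)),
    seed = sample.int(1e6, 1)))
}
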