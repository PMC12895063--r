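# Row classes for sex-aware denominators: "A" autosome, "X", "Y".
snp_row_class <- function(chrom, sex_chr, ignore_sex = FALSE) {
  if (ignore_sex) return(rep("A", length(chrom)))
  cls <- rep("A", length(chrom))
  cls[chrom == sex_chr[1]] <- "X"
  cls[chrom == sex_chr[2]] <- "Y"
  cls
}

#' Per-SNP allele frequency and missingness statistics
#'
#' For autosomal and X-chromosome SNPs every individual enters the
#' denominator; for Y-chromosome SNPs only males do, since females should
#' not carry Y variants. Frequencies count copies of `allele1` over
#' `2 * n_obs` (pseudo-haploid 0/2 coding still yields correct
#' frequencies). An all-missing SNP has `freq = NA`.
#'
#' @param values Integer genotype matrix (SNP rows x individual columns).
#' @param chrom Integer chromosome code per row.
#' @param sex Character sex code (`M`/`F`/`U`) per column.
#' @param sex_chr Integer pair of (X, Y) chromosome codes.
#' @param ignore_sex Treat every SNP autosomally (all individuals count).
#' @param ignore_unknown Drop sex `U` individuals from X/Y denominators.
#' @return Data frame with one row per SNP: `n_considered`, `n_obs`,
#'   `ref_count`, `freq`, `maf`, `missing_rate`.
#' @export
snp_stats <- function(values, chrom, sex, sex_chr = c(23L, 24L),
                      ignore_sex = FALSE, ignore_unknown = FALSE) {
  stopifnot(nrow(values) == length(chrom), ncol(values) == length(sex))
  cls <- snp_row_class(chrom, sex_chr, ignore_sex)
  cols_for <- function(cl) {
    switch(cl,
           A = rep(TRUE, length(sex)),
           X = if (ignore_unknown) sex != "U" else rep(TRUE, length(sex)),
           Y = if (ignore_unknown) sex == "M" else sex == "M")
  }
  n <- nrow(values)
  n_considered <- integer(n); n_obs <- integer(n); ref_count <- numeric(n)
  for (cl in unique(cls)) {
    rows <- cls == cl
    cc <- cols_for(cl)
    v <- values[rows, cc, drop = FALSE]
    obs <- v != 9L
    n_considered[rows] <- sum(cc)
    n_obs[rows] <- as.integer(rowSums(obs))
    ref_count[rows] <- rowSums(v * obs)
  }
  freq <- ifelse(n_obs > 0L, ref_count / (2 * n_obs), NA_real_)
  # MAF from allele counts, not 1 - freq: min(k, 2n-k)/(2n) is exact at
  # boundary values such as 1/6, where 1 - 5/6 loses an ulp
  maf <- ifelse(n_obs > 0L,
                pmin(ref_count, 2 * n_obs - ref_count) / (2 * n_obs), NA_real_)
  data.frame(n_considered = n_considered, n_obs = n_obs, ref_count = ref_count,
             freq = freq, maf = maf,
             missing_rate = ifelse(n_considered > 0L,
                                   (n_considered - n_obs) / n_considered, NA_real_))
}

#' Create an accumulator for per-individual missingness
#'
#' Per-individual missing rates are accumulated chunk by chunk over the
#' SNPs that survive SNP-level selection. Y-chromosome SNPs are excluded
#' from the denominator of non-male individuals (the per-individual mirror
#' of the male-only per-SNP rule); with `ignore_unknown`, X and Y SNPs are
#' also excluded for sex `U` individuals.
#'
#' @param sex Character sex code per retained individual column.
#' @param sex_chr Integer pair of (X, Y) chromosome codes.
#' @param ignore_sex Treat every SNP autosomally.
#' @param ignore_unknown Exclude sex `U` individuals from X/Y denominators.
#' @return List with functions `add(values, chrom)` and `result()`; the
#'   result is a data frame with `n_considered`, `n_missing`, `missing_rate`
#'   (`NA` with a warning when an individual has an empty denominator).
#' @export
ind_missing_accumulator <- function(sex, sex_chr = c(23L, 24L),
                                    ignore_sex = FALSE, ignore_unknown = FALSE) {
  n_considered <- integer(length(sex))
  n_missing <- integer(length(sex))
  counts_for <- function(cl) {
    switch(cl,
           A = rep(TRUE, length(sex)),
           X = if (ignore_unknown) sex != "U" else rep(TRUE, length(sex)),
           Y = sex == "M")
  }
  list(
    add = function(values, chrom) {
      stopifnot(nrow(values) == length(chrom), ncol(values) == length(sex))
      cls <- snp_row_class(chrom, sex_chr, ignore_sex)
      for (cl in unique(cls)) {
        rows <- cls == cl
        cc <- counts_for(cl)
        n_considered[cc] <<- n_considered[cc] + sum(rows)
        miss <- as.integer(colSums(values[rows, cc, drop = FALSE] == 9L))
        n_missing[cc] <<- n_missing[cc] + miss
      }
      invisible(NULL)
    },
    result = function() {
      if (any(n_considered == 0L))
        warning(sprintf("%d individual(s) with no SNPs in their missingness denominator",
                        sum(n_considered == 0L)), call. = FALSE)
      data.frame(n_considered = n_considered, n_missing = n_missing,
                 missing_rate = ifelse(n_considered > 0L,
                                       n_missing / n_considered, NA_real_))
    })
}

#' Set biologically impossible sex-chromosome genotypes to missing
#'
#' Y-chromosome genotypes of non-male (`F`/`U`) individuals and
#' heterozygous X-chromosome genotypes of males are replaced by the missing
#' code 9. Autosomal rows are untouched.
#'
#' @param values Integer genotype matrix (chunk rows x individuals).
#' @param chrom Integer chromosome code per row.
#' @param sex Character sex code per column.
#' @param sex_chr Integer pair of (X, Y) chromosome codes.
#' @return List with `values` (new matrix) and `n_changed`.
#' @export
sex_chr_sanitize <- function(values, chrom, sex, sex_chr = c(23L, 24L)) {
  out <- values
  y_rows <- which(chrom == sex_chr[2])
  x_rows <- which(chrom == sex_chr[1])
  n_changed <- 0L
  if (length(y_rows)) {
    nonmale <- sex != "M"
    block <- out[y_rows, nonmale, drop = FALSE]
    n_changed <- n_changed + sum(block != 9L)
    block[] <- 9L
    out[y_rows, nonmale] <- block
  }
  if (length(x_rows)) {
    male <- sex == "M"
    block <- out[x_rows, male, drop = FALSE]
    het <- block == 1L
    n_changed <- n_changed + sum(het)
    block[het] <- 9L
    out[x_rows, male] <- block
  }
  list(values = out, n_changed = n_changed)
}

#' Keep decision for the per-SNP missingness filter
#'
#' A SNP is removed when its missing rate strictly exceeds the threshold
#' (PLINK-style `--geno` convention: the boundary value is kept).
#'
#' @param stats Data frame from [snp_stats()].
#' @param threshold Maximum tolerated missing rate in `[0, 1]`.
#' @return Logical keep decision per SNP.
#' @export
filter_geno <- function(stats, threshold) {
  if (!is.numeric(threshold) || is.na(threshold) || threshold < 0 || threshold > 1)
    stop_es("--geno threshold must be in [0, 1]")
  stats$missing_rate <= threshold | is.na(stats$missing_rate)
}

#' Keep decision for the minor-allele-frequency filter
#'
#' Bounds are inclusive: a SNP is kept when `min_maf <= maf <= max_maf`
#' for whichever bounds are given. The MAF of an all-missing SNP is
#' treated as 0, so any positive `min_maf` removes it.
#'
#' @param stats Data frame from [snp_stats()].
#' @param min_maf,max_maf Bounds in `[0, 0.5]` (either may be `NULL`).
#' @return List with `keep` (logical) and `reason` (`"min-maf"`/`"max-maf"`,
#'   `NA` where kept).
#' @export
filter_maf <- function(stats, min_maf = NULL, max_maf = NULL) {
  for (b in c(min_maf, max_maf))
    if (!is.numeric(b) || is.na(b) || b < 0 || b > 0.5)
      stop_es("MAF bounds must be in [0, 0.5]")
  if (!is.null(min_maf) && !is.null(max_maf) && min_maf > max_maf)
    stop_es("--min-maf exceeds --max-maf")
  maf <- ifelse(is.na(stats$maf), 0, stats$maf)
  keep <- rep(TRUE, nrow(stats))
  reason <- rep(NA_character_, nrow(stats))
  if (!is.null(min_maf)) {
    bad <- maf < min_maf
    reason[bad] <- "min-maf"
    keep <- keep & !bad
  }
  if (!is.null(max_maf)) {
    bad <- maf > max_maf & keep
    reason[bad] <- "max-maf"
    keep <- keep & !bad
  }
  list(keep = keep, reason = reason)
}
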