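#' Per-row seeds for chunk-invariant pseudo-haploidization
#'
#' Random draws are keyed to the absolute SNP row and the individual
#' column, so the result is invariant to chunk boundaries: one seed per SNP
#' row is derived from the master seed up front (O(n_snp) metadata), and
#' each row draws one uniform per individual from its own seed.
#'
#' @param seed Master integer seed.
#' @param n_snp Total number of SNP rows in the dataset.
#' @return Integer vector of `n_snp` row seeds.
#' @export
haploid_row_seeds <- function(seed, n_snp) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n_snp, replace = TRUE)
}

#' Randomly pseudo-haploidize a genotype chunk
#'
#' Every heterozygous call (1) is replaced by one of the two homozygotes
#' (0 or 2) with probability one half, independently; 0, 2 and the missing
#' code 9 are untouched. Standard for low-coverage ancient DNA, where
#' diploid calls are unreliable. Deterministic given the row seeds and
#' column index, hence invariant to chunk size and to which columns happen
#' to be heterozygous.
#'
#' @param values Integer genotype matrix (chunk rows x individuals).
#' @param row_seeds Integer seed per chunk row, the corresponding slice of
#'   [haploid_row_seeds()].
#' @return New genotype matrix with no heterozygous calls.
#' @export
random_haploidise <- function(values, row_seeds) {
  stopifnot(nrow(values) == length(row_seeds))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  out <- values
  n_ind <- ncol(values)
  for (i in seq_len(nrow(values))) {
    het <- out[i, ] == 1L
    if (!any(het)) next
    set.seed(row_seeds[i])
    u <- runif(n_ind)  # full row drawn so draws stay keyed to column index
    out[i, het] <- ifelse(u[het] > 0.5, 2L, 0L)
  }
  out
}

#' Resolve a polarization source
#'
#' The `--polarize` argument is either a path to a two-column file of SNP
#' IDs and ancestral alleles (FILE mode) or the sample ID of a reference
#' individual in the dataset (SAMPLE mode); an existing file path selects
#' FILE mode. In SAMPLE mode the reference individual's genotype column is
#' extracted in a prior streaming pass.
#'
#' @param arg The `--polarize` argument.
#' @param handle An `es_dataset` from [es_open()].
#' @param chunk_size Chunk size for the SAMPLE-mode extraction pass.
#' @return List with `mode` (`"FILE"`/`"SAMPLE"`) and either `table`
#'   (named ancestral-allele vector) or `ref_geno` (integer vector, one
#'   genotype per SNP) plus `sample_id`.
#' @export
resolve_polarize_source <- function(arg, handle, chunk_size = 1000L) {
  if (file.exists(arg)) {
    tab <- read_mapping(arg)
    return(list(mode = "FILE", table = tab))
  }
  j <- match(arg, handle$ind$sample_id)
  if (is.na(j))
    stop_es("polarization reference '", arg,
            "' is neither an existing file nor a sample ID in .ind")
  ref <- integer(handle$n_snp)
  rd <- es_chunk_reader(handle, chunk_size)
  while (!is.null(ch <- rd()))
    ref[ch$row_offset + seq_len(nrow(ch$values))] <- ch$values[, j]
  list(mode = "SAMPLE", ref_geno = ref, sample_id = arg)
}

#' Ancestral allele per SNP row from a polarization source
#'
#' @param source List from [resolve_polarize_source()].
#' @param snp_slice Data frame of the chunk's SNP records.
#' @param ref_slice SAMPLE mode only: the reference genotypes for these rows.
#' @return List with `ancestral` (character, `NA` where undetermined) and
#'   `reason` (`"polarize-het"`, `"polarize-missing"`, `NA` otherwise).
#' @keywords internal
ancestral_for_slice <- function(source, snp_slice, ref_slice = NULL) {
  n <- nrow(snp_slice)
  reason <- rep(NA_character_, n)
  if (source$mode == "FILE") {
    anc <- unname(source$table[snp_slice$snp_id])
  } else {
    anc <- rep(NA_character_, n)
    anc[ref_slice == 2L] <- snp_slice$allele1[ref_slice == 2L]
    anc[ref_slice == 0L] <- snp_slice$allele2[ref_slice == 0L]
    reason[ref_slice == 1L] <- "polarize-het"
    reason[ref_slice == 9L] <- "polarize-missing"
  }
  list(ancestral = anc, reason = reason)
}

#' Polarize a genotype chunk to ancestral/derived orientation
#'
#' Re-orients each SNP so that `allele1` is the ancestral allele: where the
#' stated ancestral allele already equals `allele1` nothing changes; where
#' it equals `allele2` the alleles are swapped and every non-missing
#' genotype `g` is recoded `2 - g`. SNPs whose ancestral state cannot be
#' determined are excluded with a reason: reference individual heterozygous
#' (`polarize-het`) or missing (`polarize-missing`), or the ancestral
#' character absent from the table / matching neither allele
#' (`polarize-unmatched`). Matching is case-insensitive; complements are
#' not auto-resolved (run strand flipping first).
#'
#' @param values Integer genotype matrix (chunk rows x individuals).
#' @param snp_slice Data frame of the chunk's SNP records.
#' @param source List from [resolve_polarize_source()].
#' @param ref_slice SAMPLE mode: reference genotypes for these rows.
#' @return List with `values`, `snp` (kept rows only, alleles updated),
#'   `keep` (logical over input rows) and `reason` (per input row).
#' @export
polarize_chunk <- function(values, snp_slice, source, ref_slice = NULL) {
  a <- ancestral_for_slice(source, snp_slice, ref_slice)
  anc <- toupper(a$ancestral)
  reason <- a$reason
  match1 <- !is.na(anc) & anc == toupper(snp_slice$allele1)
  match2 <- !is.na(anc) & !match1 & anc == toupper(snp_slice$allele2)
  unmatched <- is.na(reason) & !match1 & !match2
  reason[unmatched] <- "polarize-unmatched"
  keep <- match1 | match2
  out <- values
  if (any(match2)) {
    block <- out[match2, , drop = FALSE]
    obs <- block != 9L
    block[obs] <- 2L - block[obs]
    out[match2, ] <- block
    tmp <- snp_slice$allele1[match2]
    snp_slice$allele1[match2] <- snp_slice$allele2[match2]
    snp_slice$allele2[match2] <- tmp
  }
  list(values = out[keep, , drop = FALSE],
       snp = snp_slice[keep, , drop = FALSE],
       keep = keep, reason = reason)
}
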