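#' Read a two-column mapping file
#'
#' Whitespace-delimited, exactly two tokens per non-empty line. Duplicate
#' keys are an error.
#'
#' @param path Path to the mapping file.
#' @return Named character vector (names are keys).
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  toks <- split_ws(lines[keep])
  nt <- lengths(toks)
  if (any(nt != 2L)) {
    i <- which(nt != 2L)[1]
    stop_es(sprintf("mapping file parse error at line %d: expected 2 columns, found %d",
                    lineno[i], nt[i]))
  }
  m <- matrix(unlist(toks), ncol = 2L, byrow = TRUE)
  if (anyDuplicated(m[, 1])) {
    stop_es("duplicate key in mapping file: ", m[duplicated(m[, 1]), 1][1])
  }
  stats::setNames(m[, 2], m[, 1])
}

#' Relabel individual populations from a mapping
#'
#' Individuals whose sample ID appears in the mapping get the mapped
#' population label; all others are untouched. Mapping keys absent from the
#' dataset produce a warning.
#'
#' @param ind Data frame from [read_ind()].
#' @param mapping Named character vector (sample ID -> new population).
#' @return List with `ind` (updated data frame) and `changed` (count).
#' @export
update_ind_pop <- function(ind, mapping) {
  hit <- ind$sample_id %in% names(mapping)
  unmatched <- setdiff(names(mapping), ind$sample_id)
  if (length(unmatched))
    warning(sprintf("%d mapping key(s) not found in .ind (first: '%s')",
                    length(unmatched), unmatched[1]), call. = FALSE)
  ind$population[hit] <- unname(mapping[ind$sample_id[hit]])
  list(ind = ind, changed = sum(hit))
}

#' Rename SNP identifiers from a mapping
#'
#' As [update_ind_pop()] but keyed on SNP ID; renaming that would create a
#' duplicate SNP ID is an error.
#'
#' @param snp Data frame from [read_snp()].
#' @param mapping Named character vector (old SNP ID -> new SNP ID).
#' @return List with `snp` (updated data frame) and `changed` (count).
#' @export
update_snp_ids <- function(snp, mapping) {
  hit <- snp$snp_id %in% names(mapping)
  unmatched <- setdiff(names(mapping), snp$snp_id)
  if (length(unmatched))
    warning(sprintf("%d mapping key(s) not found in .snp (first: '%s')",
                    length(unmatched), unmatched[1]), call. = FALSE)
  new_ids <- snp$snp_id
  new_ids[hit] <- unname(mapping[snp$snp_id[hit]])
  if (anyDuplicated(new_ids))
    stop_es("SNP ID update would create duplicate ID: ",
            new_ids[duplicated(new_ids)][1])
  snp$snp_id <- new_ids
  list(snp = snp, changed = sum(hit))
}

#' Read a recombination map file
#'
#' Whitespace-delimited columns: chromosome, physical position (bp),
#' genetic position. A header line is skipped automatically when its second
#' column is non-numeric.
#'
#' @param path Path to the map file.
#' @return Data frame with columns `chrom`, `physical_pos`, `genetic_pos`,
#'   sorted by chromosome then physical position.
#' @export
read_genetic_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_es("genetic map file is empty: ", path)
  toks <- split_ws(lines)
  if (length(toks[[1]]) >= 2 && is.na(suppressWarnings(as.numeric(toks[[1]][2]))))
    toks <- toks[-1]
  nt <- lengths(toks)
  if (any(nt < 3L))
    stop_es("genetic map parse error: expected 3 columns (chrom, physical, genetic)")
  m <- matrix(unlist(lapply(toks, `[`, 1:3)), ncol = 3L, byrow = TRUE)
  chrom <- suppressWarnings(as.integer(sub("^[Cc][Hh][Rr]", "", m[, 1])))
  phys <- suppressWarnings(as.numeric(m[, 2]))
  gen <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(chrom) || anyNA(phys) || anyNA(gen))
    stop_es("genetic map parse error: non-numeric value")
  d <- data.frame(chrom = chrom, physical_pos = phys, genetic_pos = gen)
  d[order(d$chrom, d$physical_pos), , drop = FALSE]
}

#' Re-interpolate genetic positions from a recombination map
#'
#' Replaces each SNP's genetic position by linear interpolation between the
#' bracketing map points on its chromosome. Positions outside the map range
#' are clamped to the first/last map value (extrapolation could produce
#' negative genetic distances). The `.snp` genetic column is stored in
#' Morgans; map files in centimorgans (`map_unit = "cM"`, the default) are
#' divided by 100.
#'
#' @param snp Data frame from [read_snp()].
#' @param map Data frame from [read_genetic_map()].
#' @param map_unit Unit of the map file's genetic column: `"cM"` or `"M"`.
#' @return List with `snp` (updated) and `n_unmapped` (SNPs on chromosomes
#'   absent from the map, left unchanged with a warning).
#' @export
interpolate_genetic_map <- function(snp, map, map_unit = c("cM", "M")) {
  map_unit <- match.arg(map_unit)
  gen <- if (map_unit == "cM") map$genetic_pos / 100 else map$genetic_pos
  out <- snp$genetic_pos
  n_unmapped <- 0L
  for (ch in unique(snp$chrom)) {
    rows <- snp$chrom == ch
    pts <- which(map$chrom == ch)
    if (!length(pts)) {
      n_unmapped <- n_unmapped + sum(rows)
      next
    }
    if (length(pts) < 2L)
      stop_es(sprintf("genetic map has fewer than 2 points on chromosome %d", ch))
    out[rows] <- approx(map$physical_pos[pts], gen[pts],
                        xout = snp$physical_pos[rows],
                        method = "linear", rule = 2, ties = "ordered")$y
  }
  if (n_unmapped)
    warning(sprintf("%d SNP(s) on chromosomes absent from the genetic map left unchanged",
                    n_unmapped), call. = FALSE)
  snp$genetic_pos <- out
  list(snp = snp, n_unmapped = n_unmapped)
}

WATSON_CRICK <- c(A = "T", C = "G", G = "C", T = "A")

#' Flip listed SNPs to the complementary strand
#'
#' Replaces both alleles of each listed SNP by their Watson-Crick
#' complement; genotypes are untouched. Listed SNPs with non-ACGT alleles
#' are skipped with a warning.
#'
#' @param snp Data frame from [read_snp()].
#' @param snp_ids Character vector of SNP IDs to flip.
#' @return List with `snp` (updated), `flipped` (count) and `skipped` (count).
#' @export
flip_strand <- function(snp, snp_ids) {
  listed <- snp$snp_id %in% snp_ids
  ok <- toupper(snp$allele1) %in% names(WATSON_CRICK) &
    toupper(snp$allele2) %in% names(WATSON_CRICK)
  skip <- listed & !ok
  if (any(skip))
    warning(sprintf("%d listed SNP(s) with non-ACGT alleles not flipped (first: '%s')",
                    sum(skip), snp$snp_id[skip][1]), call. = FALSE)
  do <- listed & ok
  snp$allele1[do] <- chartr("ACGTacgt", "TGCAtgca", snp$allele1[do])
  snp$allele2[do] <- chartr("ACGTacgt", "TGCAtgca", snp$allele2[do])
  list(snp = snp, flipped = sum(do), skipped = sum(skip))
}

backup_then_write <- function(path, write_fn) {
  backup <- paste0(path, ".backup")
  if (file.exists(backup))
    stop_es(backup, " already exists; move or remove it before updating in place")
  if (!file.copy(path, backup, copy.date = TRUE))
    stop_es("could not create backup ", backup)
  write_fn(path)
  invisible(backup)
}
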