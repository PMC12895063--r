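read_id_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines)]
}

#' Build the global individual inclusion mask
#'
#' Starting from all-included, population-level keep/remove lists are
#' applied first, then individual-level lists, so an individual exclusion
#' can refine a population inclusion. Keep and remove lists of the same
#' kind are contradictory and refused. Names absent from the dataset warn.
#'
#' @param ind Data frame from [read_ind()].
#' @param keep_indv,remove_indv Character vectors of sample IDs (or `NULL`).
#' @param keep_pop,remove_pop Character vectors of population labels (or `NULL`).
#' @return Logical vector aligned with `.ind` order; computed once and
#'   applied to every chunk's columns.
#' @export
build_individual_mask <- function(ind, keep_indv = NULL, remove_indv = NULL,
                                  keep_pop = NULL, remove_pop = NULL) {
  if (!is.null(keep_indv) && !is.null(remove_indv))
    stop_es("--keep-indv and --remove-indv are contradictory; give one")
  if (!is.null(keep_pop) && !is.null(remove_pop))
    stop_es("--keep-pop and --remove-pop are contradictory; give one")
  warn_unknown <- function(x, universe, what) {
    miss <- setdiff(x, universe)
    if (length(miss))
      warning(sprintf("%d %s in list not present in .ind (first: '%s')",
                      length(miss), what, miss[1]), call. = FALSE)
  }
  mask <- rep(TRUE, nrow(ind))
  if (!is.null(keep_pop)) {
    warn_unknown(keep_pop, ind$population, "population(s)")
    mask <- mask & ind$population %in% keep_pop
  }
  if (!is.null(remove_pop)) {
    warn_unknown(remove_pop, ind$population, "population(s)")
    mask <- mask & !(ind$population %in% remove_pop)
  }
  if (!is.null(keep_indv)) {
    warn_unknown(keep_indv, ind$sample_id, "sample ID(s)")
    mask <- mask & ind$sample_id %in% keep_indv
  }
  if (!is.null(remove_indv)) {
    warn_unknown(remove_indv, ind$sample_id, "sample ID(s)")
    mask <- mask & !(ind$sample_id %in% remove_indv)
  }
  if (!any(mask)) stop_es("no individuals remain after individual/population filtering")
  mask
}

chrom_token <- function(item, sex_chr) {
  tok <- sub("^[Cc][Hh][Rr]", "", trimws(item))
  if (toupper(tok) == "X") return(sex_chr[1])
  if (toupper(tok) == "Y") return(sex_chr[2])
  v <- suppressWarnings(as.integer(tok))
  if (is.na(v) || v < 0L) stop_es("cannot parse chromosome token '", item, "'")
  v
}

#' Parse a chromosome specification
#'
#' Accepts comma-separated items; each item is a single chromosome code or
#' an inclusive range `a-b` (hyphen or en-dash). A `chr` prefix is stripped
#' case-insensitively; `X`/`Y` map to the configured sex-chromosome codes.
#'
#' @param text Specification such as `"1,2,5-6,22"` or `"chr1,chrX"`.
#' @param sex_chr Integer pair of (X, Y) chromosome codes, default `c(23, 24)`.
#' @return Sorted integer vector of chromosome codes.
#' @export
parse_chrom_spec <- function(text, sex_chr = c(23L, 24L)) {
  items <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (!length(items) || any(!nzchar(trimws(items))))
    stop_es("empty item in chromosome specification '", text, "'")
  out <- integer(0)
  for (item in items) {
    parts <- strsplit(trimws(item), "[-\u2013]")[[1]]
    if (length(parts) == 1L) {
      out <- c(out, chrom_token(parts, sex_chr))
    } else if (length(parts) == 2L) {
      a <- chrom_token(parts[1], sex_chr)
      b <- chrom_token(parts[2], sex_chr)
      if (b < a) stop_es("reversed chromosome range '", item, "'")
      out <- c(out, seq.int(a, b))
    } else {
      stop_es("cannot parse chromosome item '", item, "'")
    }
  }
  sort(unique(out))
}

strip_digit_seps <- function(x) gsub("[ ,\u2009\u202f\u00a0]", "", x)

#' Parse genomic region specifications into a region set
#'
#' Regions come from inline strings `"CHR:START-END"` (digits may contain
#' spaces or commas as group separators; hyphen or en-dash as the range
#' separator) and/or interval files with whitespace-delimited columns
#' (chrom, start, end). Coordinates are 1-based inclusive, except that
#' files with a `.bed` extension are read as 0-based half-open and
#' converted. Point-overlap queries are served by an interval index
#' (IRanges).
#'
#' @param specs Character vector of inline region strings (or `NULL`).
#' @param files Character vector of interval file paths (or `NULL`).
#' @param sex_chr Integer pair of (X, Y) codes for `X`/`Y` chromosome names.
#' @return An object of class `es_region_set`.
#' @export
parse_region_spec <- function(specs = NULL, files = NULL, sex_chr = c(23L, 24L)) {
  chrom <- integer(0); start <- numeric(0); end <- numeric(0)
  add <- function(ch, s, e, label) {
    if (is.na(s) || is.na(e)) stop_es("malformed region '", label, "'")
    if (s > e) stop_es("region start exceeds end in '", label, "'")
    chrom <<- c(chrom, ch); start <<- c(start, s); end <<- c(end, e)
  }
  for (sp in specs) {
    parts <- strsplit(sp, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop_es("malformed region '", sp, "' (expected CHR:START-END)")
    ch <- chrom_token(parts[1], sex_chr)
    se <- strsplit(strip_digit_seps(parts[2]), "[-\u2013]")[[1]]
    if (length(se) != 2L) stop_es("malformed region '", sp, "' (expected CHR:START-END)")
    add(ch, suppressWarnings(as.numeric(se[1])), suppressWarnings(as.numeric(se[2])), sp)
  }
  for (f in files) {
    is_bed <- grepl("\\.bed$", f, ignore.case = TRUE)
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    toks <- split_ws(lines)
    for (i in seq_along(toks)) {
      tk <- toks[[i]]
      if (length(tk) < 3L)
        stop_es(sprintf("interval file %s line %d: expected >= 3 columns", f, i))
      ch <- chrom_token(tk[1], sex_chr)
      s <- suppressWarnings(as.numeric(strip_digit_seps(tk[2])))
      e <- suppressWarnings(as.numeric(strip_digit_seps(tk[3])))
      if (is_bed && !is.na(s)) s <- s + 1  # BED is 0-based half-open
      add(ch, s, e, paste(tk[1:3], collapse = " "))
    }
  }
  idx <- lapply(split(seq_along(chrom), chrom), function(i)
    IRanges::IRanges(start = start[i], end = end[i]))
  structure(list(chrom = chrom, start = start, end = end, index = idx),
            class = "es_region_set")
}

#' Query a region set for point overlap
#'
#' @param regions An `es_region_set` from [parse_region_spec()].
#' @param chrom Integer vector of chromosome codes.
#' @param pos Numeric vector of 1-based positions (same length).
#' @return Logical vector: does each point fall inside some interval?
#' @export
region_overlap <- function(regions, chrom, pos) {
  stopifnot(inherits(regions, "es_region_set"))
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    ir <- regions$index[[as.character(ch)]]
    if (is.null(ir)) next
    i <- which(chrom == ch)
    out[i] <- IRanges::overlapsAny(IRanges::IRanges(start = pos[i], width = 1L), ir)
  }
  out
}

#' SNP selection mask for one chunk
#'
#' Applies, in order, SNP-ID keep/remove sets, then region keep/remove,
#' then chromosome keep/remove. Returns the keep mask plus the removal
#' reason (`"snp-list"`, `"region"` or `"chromosome"`) for dropped rows.
#'
#' @param snp_slice Data frame of the chunk's SNP records.
#' @param keep_snps,remove_snps Character vectors of SNP IDs (or `NULL`).
#' @param regions_keep,regions_remove `es_region_set` objects (or `NULL`).
#' @param chrom_keep,chrom_remove Integer vectors of chromosome codes (or `NULL`).
#' @return List with `keep` (logical) and `reason` (character, `NA` where kept).
#' @export
snp_selection_mask <- function(snp_slice, keep_snps = NULL, remove_snps = NULL,
                               regions_keep = NULL, regions_remove = NULL,
                               chrom_keep = NULL, chrom_remove = NULL) {
  n <- nrow(snp_slice)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  drop <- function(bad, why) {
    bad <- bad & keep
    reason[bad] <<- why
    keep[bad] <<- FALSE
  }
  if (!is.null(keep_snps)) drop(!(snp_slice$snp_id %in% keep_snps), "snp-list")
  if (!is.null(remove_snps)) drop(snp_slice$snp_id %in% remove_snps, "snp-list")
  if (!is.null(regions_keep))
    drop(!region_overlap(regions_keep, snp_slice$chrom, snp_slice$physical_pos), "region")
  if (!is.null(regions_remove))
    drop(region_overlap(regions_remove, snp_slice$chrom, snp_slice$physical_pos), "region")
  if (!is.null(chrom_keep)) drop(!(snp_slice$chrom %in% chrom_keep), "chromosome")
  if (!is.null(chrom_remove)) drop(snp_slice$chrom %in% chrom_remove, "chromosome")
  list(keep = keep, reason = reason)
}
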