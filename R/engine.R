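#' Assemble and validate a pipeline configuration
#'
#' Resolves the full flag set into a validated configuration and decides
#' the operation mode. Update-only mode (in-place metadata edits with
#' `.backup` copies, genotypes never read) is entered when only update
#' options are given and no output prefix; any processing flag or `out`
#' switches to processing mode, where all results go to new output files
#' and the inputs are left untouched.
#'
#' @param prefix Common input prefix (`.geno`/`.snp`/`.ind` appended).
#' @param geno,snp,ind Explicit input paths (override `prefix`).
#' @param out Output prefix; required in processing mode.
#' @param out_format `"eigenstrat"` (text) or `"ancestrymap"` (packed binary).
#' @param chunk_size SNP rows per chunk (default 1000).
#' @param update_ind,update_snp Two-column mapping files (sample ID -> new
#'   population; old SNP ID -> new SNP ID).
#' @param genetic_map Recombination map file for re-interpolating genetic
#'   positions.
#' @param map_unit Unit of the map file's genetic column, `"cM"` or `"M"`.
#' @param flip_strand File of SNP IDs whose alleles are complemented.
#' @param keep_indv,remove_indv,keep_pop,remove_pop Files listing sample
#'   IDs / population labels, one per line.
#' @param keep_snps,remove_snps Files listing SNP IDs, one per line.
#' @param keep_region,remove_region Character vector of interval files
#'   and/or inline `"CHR:START-END"` specifications.
#' @param keep_chr,remove_chr Chromosome specifications such as `"1-22"`.
#' @param geno_threshold Maximum per-SNP missing rate (`--geno`).
#' @param min_maf,max_maf Inclusive minor-allele-frequency bounds.
#' @param freq,missing Write the `.frq` / `.imiss` statistics tables.
#' @param sex_chr Comma-separated X,Y chromosome codes (default `"23,24"`).
#' @param sex_chr_missing Set impossible sex-chromosome genotypes to missing.
#' @param ignore_sex Disable all sex-aware denominator rules.
#' @param ignore_unknown Drop sex `U` individuals from X/Y denominators.
#' @param random_haploidise Randomly pseudo-haploidize heterozygous calls.
#' @param seed Integer seed for the haploidization draws (logged).
#' @param polarize Polarization source: ancestral-allele file or sample ID.
#' @param verbose Also write the per-SNP removal log (`.removed.snp`).
#' @return An object of class `es_config`.
#' @export
es_config <- function(prefix = NULL, geno = NULL, snp = NULL, ind = NULL,
                      out = NULL, out_format = c("eigenstrat", "ancestrymap"),
                      chunk_size = 1000L,
                      update_ind = NULL, update_snp = NULL,
                      genetic_map = NULL, map_unit = "cM", flip_strand = NULL,
                      keep_indv = NULL, remove_indv = NULL,
                      keep_pop = NULL, remove_pop = NULL,
                      keep_snps = NULL, remove_snps = NULL,
                      keep_region = NULL, remove_region = NULL,
                      keep_chr = NULL, remove_chr = NULL,
                      geno_threshold = NULL, min_maf = NULL, max_maf = NULL,
                      freq = FALSE, missing = FALSE,
                      sex_chr = "23,24", sex_chr_missing = FALSE,
                      ignore_sex = FALSE, ignore_unknown = FALSE,
                      random_haploidise = FALSE, seed = 42L,
                      polarize = NULL, verbose = FALSE) {
  out_format <- match.arg(out_format)
  map_unit <- match.arg(map_unit, c("cM", "M"))
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    stop_es("--chunk-size must be a positive integer", class = "es_usage_error")
  if (!is.null(geno_threshold) &&
      (!is.numeric(geno_threshold) || is.na(geno_threshold) ||
       geno_threshold < 0 || geno_threshold > 1))
    stop_es("--geno must be in [0, 1]", class = "es_usage_error")
  for (b in list(list("--min-maf", min_maf), list("--max-maf", max_maf))) {
    if (!is.null(b[[2]])) {
      v <- as.numeric(b[[2]])
      if (is.na(v) || v < 0 || v > 0.5)
        stop_es(b[[1]], " must be in [0, 0.5]", class = "es_usage_error")
    }
  }
  if (!is.null(min_maf) && !is.null(max_maf) && min_maf > max_maf)
    stop_es("--min-maf exceeds --max-maf", class = "es_usage_error")
  if (!is.null(keep_indv) && !is.null(remove_indv))
    stop_es("--keep-indv and --remove-indv are contradictory", class = "es_usage_error")
  if (!is.null(keep_pop) && !is.null(remove_pop))
    stop_es("--keep-pop and --remove-pop are contradictory", class = "es_usage_error")
  if (!is.null(keep_snps) && !is.null(remove_snps))
    stop_es("--keep-snps and --remove-snps are contradictory", class = "es_usage_error")
  sex_codes <- tryCatch(parse_chrom_spec(as.character(sex_chr)),
                        error = function(e)
                          stop_es("--sex-chr must be two chromosome codes",
                                  class = "es_usage_error"))
  if (length(sex_codes) != 2L)
    stop_es("--sex-chr must name exactly two codes (X,Y)", class = "es_usage_error")

  cfg <- list(prefix = prefix, geno = geno, snp = snp, ind = ind,
              out = out, out_format = out_format, chunk_size = chunk_size,
              update_ind = update_ind, update_snp = update_snp,
              genetic_map = genetic_map, map_unit = map_unit,
              flip_strand = flip_strand,
              keep_indv = keep_indv, remove_indv = remove_indv,
              keep_pop = keep_pop, remove_pop = remove_pop,
              keep_snps = keep_snps, remove_snps = remove_snps,
              keep_region = keep_region, remove_region = remove_region,
              keep_chr = keep_chr, remove_chr = remove_chr,
              geno_threshold = geno_threshold,
              min_maf = min_maf, max_maf = max_maf,
              freq = freq, missing = missing,
              sex_chr = sex_codes, sex_chr_missing = sex_chr_missing,
              ignore_sex = ignore_sex, ignore_unknown = ignore_unknown,
              random_haploidise = random_haploidise, seed = as.integer(seed),
              polarize = polarize, verbose = verbose)
  has_update <- !is.null(update_ind) || !is.null(update_snp) ||
    !is.null(genetic_map) || !is.null(flip_strand)
  has_processing <- !is.null(keep_indv) || !is.null(remove_indv) ||
    !is.null(keep_pop) || !is.null(remove_pop) ||
    !is.null(keep_snps) || !is.null(remove_snps) ||
    !is.null(keep_region) || !is.null(remove_region) ||
    !is.null(keep_chr) || !is.null(remove_chr) ||
    !is.null(geno_threshold) || !is.null(min_maf) || !is.null(max_maf) ||
    isTRUE(freq) || isTRUE(missing) || isTRUE(sex_chr_missing) ||
    isTRUE(ignore_sex) || isTRUE(ignore_unknown) ||
    isTRUE(random_haploidise) || !is.null(polarize)
  if (is.null(out) && !has_processing) {
    if (!has_update)
      stop_es("nothing to do: give update options, processing options or --out",
              class = "es_usage_error")
    cfg$mode <- "UPDATE_ONLY"
  } else {
    if (is.null(out))
      stop_es("processing mode requires --out", class = "es_usage_error")
    cfg$mode <- "PROCESSING"
  }
  structure(cfg, class = "es_config")
}

resolve_region_args <- function(args, sex_chr) {
  if (is.null(args)) return(NULL)
  is_file <- file.exists(args) & !grepl(":", args, fixed = TRUE)
  parse_region_spec(specs = args[!is_file], files = args[is_file],
                    sex_chr = sex_chr)
}

apply_metadata_updates <- function(cfg, snp, ind) {
  touched_ind <- FALSE
  touched_snp <- FALSE
  counts <- list()
  if (!is.null(cfg$update_ind)) {
    u <- update_ind_pop(ind, read_mapping(cfg$update_ind))
    ind <- u$ind; counts$ind_relabelled <- u$changed; touched_ind <- TRUE
  }
  if (!is.null(cfg$update_snp)) {
    u <- update_snp_ids(snp, read_mapping(cfg$update_snp))
    snp <- u$snp; counts$snp_renamed <- u$changed; touched_snp <- TRUE
  }
  if (!is.null(cfg$genetic_map)) {
    u <- interpolate_genetic_map(snp, read_genetic_map(cfg$genetic_map),
                                 cfg$map_unit)
    snp <- u$snp; counts$snp_unmapped <- u$n_unmapped; touched_snp <- TRUE
  }
  if (!is.null(cfg$flip_strand)) {
    u <- flip_strand(snp, read_id_list(cfg$flip_strand))
    snp <- u$snp; counts$snp_flipped <- u$flipped; touched_snp <- TRUE
  }
  list(snp = snp, ind = ind, touched_ind = touched_ind,
       touched_snp = touched_snp, counts = counts)
}

#' Run the full processing pipeline
#'
#' Operations are applied in a fixed order: (i) metadata updates, (ii)
#' allele polarization, (iii) random pseudo-haploidization, (iv)
#' individual/population filtering (global mask, applied to each chunk's
#' columns), (v) sex-chromosome handling, (vi) SNP-ID selection, (vii)
#' region/chromosome filtering, (viii) `.frq`/`.imiss` statistics, and
#' (ix) missing-rate then MAF filtering. Subsetting therefore always
#' precedes the calculations, so statistics never include individuals or
#' SNPs that are being removed. Genotypes are streamed chunk by chunk in
#' both directions; at most one chunk is resident at a time.
#'
#' In update-only mode the `.ind`/`.snp` files are rewritten in place after
#' each original is copied to `<name>.backup`; the `.geno` file is not
#' touched.
#'
#' @param config An `es_config`.
#' @return An `es_summary` with input/output counts, per-reason SNP removal
#'   totals and output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "es_config"))
  cfg <- config
  if (cfg$mode == "UPDATE_ONLY") {
    snp_path <- if (!is.null(cfg$snp)) cfg$snp else paste0(cfg$prefix, ".snp")
    ind_path <- if (!is.null(cfg$ind)) cfg$ind else paste0(cfg$prefix, ".ind")
    ind <- read_ind(ind_path)
    snp <- read_snp(snp_path)
    up <- apply_metadata_updates(cfg, snp, ind)
    if (up$touched_ind)
      backup_then_write(ind_path, function(p) write_ind(up$ind, p))
    if (up$touched_snp)
      backup_then_write(snp_path, function(p) write_snp(up$snp, p))
    res <- structure(list(mode = "UPDATE_ONLY", counts = up$counts,
                          ind_path = if (up$touched_ind) ind_path,
                          snp_path = if (up$touched_snp) snp_path),
                     class = "es_summary")
    return(invisible(res))
  }

  handle <- es_open(cfg$prefix, cfg$geno, cfg$snp, cfg$ind)
  up <- apply_metadata_updates(cfg, handle$snp, handle$ind)
  snp <- up$snp
  ind <- up$ind

  pol_src <- if (!is.null(cfg$polarize))
    resolve_polarize_source(cfg$polarize, handle, cfg$chunk_size)
  row_seeds <- if (isTRUE(cfg$random_haploidise))
    haploid_row_seeds(cfg$seed, handle$n_snp)

  mask <- build_individual_mask(
    ind,
    keep_indv = if (!is.null(cfg$keep_indv)) read_id_list(cfg$keep_indv),
    remove_indv = if (!is.null(cfg$remove_indv)) read_id_list(cfg$remove_indv),
    keep_pop = if (!is.null(cfg$keep_pop)) read_id_list(cfg$keep_pop),
    remove_pop = if (!is.null(cfg$remove_pop)) read_id_list(cfg$remove_pop))
  ind_out <- ind[mask, , drop = FALSE]
  sex <- ind_out$sex

  keep_snps <- if (!is.null(cfg$keep_snps)) read_id_list(cfg$keep_snps)
  remove_snps <- if (!is.null(cfg$remove_snps)) read_id_list(cfg$remove_snps)
  regions_keep <- resolve_region_args(cfg$keep_region, cfg$sex_chr)
  regions_remove <- resolve_region_args(cfg$remove_region, cfg$sex_chr)
  chrom_keep <- if (!is.null(cfg$keep_chr)) parse_chrom_spec(cfg$keep_chr, cfg$sex_chr)
  chrom_remove <- if (!is.null(cfg$remove_chr)) parse_chrom_spec(cfg$remove_chr, cfg$sex_chr)

  imiss <- ind_missing_accumulator(sex, cfg$sex_chr, cfg$ignore_sex,
                                   cfg$ignore_unknown)
  writer <- es_geno_writer(paste0(cfg$out, ".geno"),
                           if (cfg$out_format == "ancestrymap") "PACKED" else "TEXT",
                           nrow(ind_out))
  kept_snp <- list()
  frq_rows <- list()
  removed <- list()
  n_sanitized <- 0L

  rd <- es_chunk_reader(handle, cfg$chunk_size)
  while (!is.null(ch <- rd())) {
    vals <- ch$values
    idx <- ch$row_offset + seq_len(nrow(vals))
    snp_slice <- snp[idx, , drop = FALSE]
    # removal reasons aligned to the chunk's original rows, so the verbose
    # log comes out in dataset row order whatever the chunk size
    chunk_ids <- snp_slice$snp_id
    chunk_reason <- rep(NA_character_, length(idx))
    pos <- seq_along(idx)  # current rows -> original chunk rows

    if (!is.null(pol_src)) {                                  # (ii)
      ref_slice <- if (pol_src$mode == "SAMPLE") pol_src$ref_geno[idx]
      p <- polarize_chunk(vals, snp_slice, pol_src, ref_slice)
      chunk_reason[pos[!p$keep]] <- p$reason[!p$keep]
      vals <- p$values
      snp_slice <- p$snp
      idx <- idx[p$keep]
      pos <- pos[p$keep]
    }
    if (!is.null(row_seeds) && nrow(vals))                    # (iii)
      vals <- random_haploidise(vals, row_seeds[idx])
    vals <- vals[, mask, drop = FALSE]                        # (iv)
    if (isTRUE(cfg$sex_chr_missing) && nrow(vals)) {          # (v)
      s <- sex_chr_sanitize(vals, snp_slice$chrom, sex, cfg$sex_chr)
      vals <- s$values
      n_sanitized <- n_sanitized + s$n_changed
    }
    sel <- snp_selection_mask(snp_slice,                      # (vi)-(vii)
                              keep_snps = keep_snps, remove_snps = remove_snps,
                              regions_keep = regions_keep,
                              regions_remove = regions_remove,
                              chrom_keep = chrom_keep, chrom_remove = chrom_remove)
    chunk_reason[pos[!sel$keep]] <- sel$reason[!sel$keep]
    vals <- vals[sel$keep, , drop = FALSE]
    snp_slice <- snp_slice[sel$keep, , drop = FALSE]
    pos <- pos[sel$keep]

    if (nrow(vals)) {
      imiss$add(vals, snp_slice$chrom)                        # (viii)
      st <- snp_stats(vals, snp_slice$chrom, sex, cfg$sex_chr,
                      cfg$ignore_sex, cfg$ignore_unknown)
      if (isTRUE(cfg$freq))
        frq_rows[[length(frq_rows) + 1L]] <-
          cbind(snp_slice[, c("snp_id", "chrom", "physical_pos",
                              "allele1", "allele2")],
                st[, c("n_obs", "freq", "maf", "missing_rate")])

      keep <- rep(TRUE, nrow(vals))                           # (ix)
      if (!is.null(cfg$geno_threshold)) {
        kg <- filter_geno(st, cfg$geno_threshold)
        chunk_reason[pos[!kg]] <- "geno"
        keep <- keep & kg
      }
      if (!is.null(cfg$min_maf) || !is.null(cfg$max_maf)) {
        km <- filter_maf(st, cfg$min_maf, cfg$max_maf)
        bad <- keep & !km$keep
        chunk_reason[pos[bad]] <- km$reason[bad]
        keep <- keep & km$keep
      }
      vals <- vals[keep, , drop = FALSE]
      snp_slice <- snp_slice[keep, , drop = FALSE]
      if (nrow(vals)) {
        writer$write(vals)
        kept_snp[[length(kept_snp) + 1L]] <- snp_slice
      }
    }
    gone <- !is.na(chunk_reason)
    if (any(gone))
      removed[[length(removed) + 1L]] <-
        data.frame(snp_id = chunk_ids[gone], reason = chunk_reason[gone],
                   stringsAsFactors = FALSE)
  }
  n_out <- writer$close()
  if (n_out == 0L)
    stop_es("no SNPs remain after filtering; no output dataset written")
  snp_out <- do.call(rbind, kept_snp)
  write_snp(snp_out, paste0(cfg$out, ".snp"))
  write_ind(ind_out, paste0(cfg$out, ".ind"))

  outputs <- c(geno = paste0(cfg$out, ".geno"), snp = paste0(cfg$out, ".snp"),
               ind = paste0(cfg$out, ".ind"))
  if (isTRUE(cfg$freq)) {
    frq <- do.call(rbind, frq_rows)
    names(frq)[names(frq) == "physical_pos"] <- "pos"
    write.table(frq, paste0(cfg$out, ".frq"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs["frq"] <- paste0(cfg$out, ".frq")
  }
  imiss_df <- NULL
  if (isTRUE(cfg$missing)) {
    imiss_df <- cbind(ind_out[, c("sample_id", "population")], imiss$result())
    write.table(imiss_df, paste0(cfg$out, ".imiss"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs["imiss"] <- paste0(cfg$out, ".imiss")
  }
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(snp_id = character(0), reason = character(0))
  if (isTRUE(cfg$verbose)) {
    write.table(removed_df, paste0(cfg$out, ".removed.snp"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    outputs["removed"] <- paste0(cfg$out, ".removed.snp")
  }

  res <- structure(list(
    mode = "PROCESSING",
    n_ind_in = handle$n_ind, n_ind_out = nrow(ind_out),
    n_snp_in = handle$n_snp, n_snp_out = n_out,
    removed_by_reason = if (nrow(removed_df))
      table(removed_df$reason) else table(character(0)),
    n_sanitized = n_sanitized,
    update_counts = up$counts,
    seed = cfg$seed,
    outputs = outputs,
    removed = removed_df,
    imiss = imiss_df),
    class = "es_summary")
  invisible(res)
}

#' @export
print.es_summary <- function(x, ...) {
  if (x$mode == "UPDATE_ONLY") {
    cat("update-only mode: metadata edited in place (originals in .backup)\n")
    for (nm in names(x$counts)) cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
    return(invisible(x))
  }
  cat(sprintf("individuals: %d in, %d out\n", x$n_ind_in, x$n_ind_out))
  cat(sprintf("SNPs:        %d in, %d out\n", x$n_snp_in, x$n_snp_out))
  if (length(x$removed_by_reason)) {
    cat("SNPs removed by reason:\n")
    for (nm in names(x$removed_by_reason))
      cat(sprintf("  %-20s %d\n", nm, x$removed_by_reason[[nm]]))
  }
  if (x$n_sanitized)
    cat(sprintf("sex-chromosome genotypes set to missing: %d\n", x$n_sanitized))
  cat("outputs:\n")
  for (p in x$outputs) cat(" ", p, "\n")
  invisible(x)
}
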