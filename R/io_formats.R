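# Genotype alphabet: 0/1/2 count copies of allele1, 9 is missing.
GENO_VALUES <- c(0L, 1L, 2L, 9L)

# 2-bit packed codes: 0 -> 00, 1 -> 01, 2 -> 10, 9 (missing) -> 11
geno_to_code <- function(g) ifelse(g == 9L, 3L, g)
code_to_geno <- function(code) ifelse(code == 3L, 9L, code)

packed_record_length <- function(n_ind) as.integer(max(ceiling(n_ind / 4), 48L))

stop_es <- function(..., class = "eigenstratr_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Detect the encoding of a genotype file
#'
#' A packed ANCESTRYMAP `.geno` file starts with the five ASCII bytes
#' `"GENO "`; anything else is treated as text EIGENSTRAT, in which case the
#' first line must contain only the genotype characters `0`, `1`, `2`, `9`.
#'
#' @param geno_path Path to a `.geno` file.
#' @return `"TEXT"` or `"PACKED"`.
#' @export
detect_geno_encoding <- function(geno_path) {
  if (!file.exists(geno_path)) stop_es("genotype file not found: ", geno_path)
  sz <- file.size(geno_path)
  if (is.na(sz) || sz == 0) stop_es("genotype file is empty: ", geno_path)
  con <- file(geno_path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 65536))
  if (length(head) >= 5 && rawToChar(head[1:5]) == "GENO ") return("PACKED")
  nl <- which(head == as.raw(10L))[1]
  line <- if (is.na(nl)) head else head[seq_len(nl - 1L)]
  if (length(line) && line[length(line)] == as.raw(13L))
    line <- line[-length(line)]
  ok <- line %in% as.raw(utf8ToInt("0129"))
  if (!all(ok)) {
    bad <- line[which(!ok)[1]]
    stop_es(sprintf(
      "not a genotype file: first line contains byte 0x%s ('%s'), expected only 0/1/2/9",
      toupper(as.character(bad)), rawToChar(bad)))
  }
  "TEXT"
}

split_ws <- function(x) strsplit(trimws(x), "[ \t]+")

#' Read an EIGENSTRAT individual file
#'
#' Each non-empty line holds three whitespace-delimited tokens: sample ID,
#' sex code (`M`, `F` or `U`) and population label. Unknown sex codes are
#' mapped to `U` with a warning.
#'
#' @param path Path to a `.ind` file.
#' @return A data frame with columns `sample_id`, `sex`, `population`.
#' @export
read_ind <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  toks <- split_ws(lines[keep])
  nt <- lengths(toks)
  if (any(nt != 3L)) {
    i <- which(nt != 3L)[1]
    stop_es(sprintf(".ind parse error at line %d: expected 3 columns, found %d",
                    lineno[i], nt[i]))
  }
  m <- matrix(unlist(toks), ncol = 3L, byrow = TRUE)
  sex <- m[, 2]
  bad <- !(sex %in% c("M", "F", "U"))
  if (any(bad)) {
    warning(sprintf("%d individual(s) with unrecognized sex code mapped to U (first: '%s')",
                    sum(bad), sex[bad][1]), call. = FALSE)
    sex[bad] <- "U"
  }
  data.frame(sample_id = m[, 1], sex = sex, population = m[, 3],
             stringsAsFactors = FALSE)
}

#' Write an EIGENSTRAT individual file
#' @param ind Data frame as returned by [read_ind()].
#' @param path Output path.
#' @export
write_ind <- function(ind, path) {
  writeLines(paste(ind$sample_id, ind$sex, ind$population), path)
  invisible(path)
}

#' Read an EIGENSTRAT SNP file
#'
#' Each line holds six whitespace-delimited columns: SNP ID, chromosome
#' code, genetic position (Morgans), physical position (bp) and the two
#' alleles. Four-column files without alleles are rejected because strand
#' flipping and polarization require allele information.
#'
#' @param path Path to a `.snp` file.
#' @return A data frame with columns `snp_id`, `chrom`, `genetic_pos`,
#'   `physical_pos`, `allele1`, `allele2`.
#' @export
read_snp <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  toks <- split_ws(lines[keep])
  nt <- lengths(toks)
  if (any(nt != 6L)) {
    i <- which(nt != 6L)[1]
    stop_es(sprintf(".snp parse error at line %d: expected 6 columns, found %d",
                    lineno[i], nt[i]))
  }
  m <- matrix(unlist(toks), ncol = 6L, byrow = TRUE)
  chrom <- suppressWarnings(as.integer(m[, 2]))
  gpos <- suppressWarnings(as.numeric(m[, 3]))
  ppos <- suppressWarnings(as.numeric(m[, 4]))
  for (chk in list(list(chrom, "chromosome"), list(gpos, "genetic position"),
                   list(ppos, "physical position"))) {
    if (anyNA(chk[[1]])) {
      i <- which(is.na(chk[[1]]))[1]
      stop_es(sprintf(".snp parse error at line %d: non-numeric %s '%s'",
                      lineno[i], chk[[2]],
                      m[i, c(chromosome = 2, `genetic position` = 3,
                             `physical position` = 4)[chk[[2]]]]))
    }
  }
  if (any(chrom < 0L)) {
    i <- which(chrom < 0L)[1]
    stop_es(sprintf(".snp parse error at line %d: negative chromosome code", lineno[i]))
  }
  if (any(ppos != floor(ppos))) {
    i <- which(ppos != floor(ppos))[1]
    stop_es(sprintf(".snp parse error at line %d: physical position not an integer", lineno[i]))
  }
  data.frame(snp_id = m[, 1], chrom = chrom, genetic_pos = gpos,
             physical_pos = ppos, allele1 = m[, 5], allele2 = m[, 6],
             stringsAsFactors = FALSE)
}

# Shortest decimal representation that reads back to the same double, so
# genetic positions survive any number of read/write round trips.
format_exact <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- as.numeric(out) != x
  out[bad] <- sprintf("%.17g", x[bad])
  out
}

#' Write an EIGENSTRAT SNP file
#' @param snp Data frame as returned by [read_snp()].
#' @param path Output path.
#' @export
write_snp <- function(snp, path) {
  writeLines(paste(snp$snp_id, snp$chrom, format_exact(snp$genetic_pos),
                   sprintf("%.0f", snp$physical_pos), snp$allele1, snp$allele2),
             path)
  invisible(path)
}

parse_packed_header <- function(raw_header) {
  txt <- rawToChar(raw_header[raw_header != as.raw(0L)])
  toks <- strsplit(trimws(txt), "[ \t]+")[[1]]
  if (length(toks) < 3L || toks[1] != "GENO")
    stop_es("invalid packed ANCESTRYMAP header: ", txt)
  list(n_ind = as.integer(toks[2]), n_snp = as.integer(toks[3]))
}

#' Open an EIGENSTRAT dataset
#'
#' Resolves the three file paths (either from a common prefix or given
#' individually), auto-detects the genotype encoding, reads the `.snp` and
#' `.ind` metadata, and cross-checks dimensions. For packed files the header
#' counts and file size are validated; for text files the first genotype
#' line must have one character per individual.
#'
#' @param prefix Common path prefix; `.geno`, `.snp`, `.ind` are appended.
#' @param geno,snp,ind Explicit file paths (override `prefix`).
#' @return An object of class `es_dataset` with elements `geno_path`,
#'   `snp_path`, `ind_path`, `encoding`, `n_ind`, `n_snp`, `snp`, `ind`.
#' @export
es_open <- function(prefix = NULL, geno = NULL, snp = NULL, ind = NULL) {
  if (!is.null(prefix)) {
    if (is.null(geno)) geno <- paste0(prefix, ".geno")
    if (is.null(snp)) snp <- paste0(prefix, ".snp")
    if (is.null(ind)) ind <- paste0(prefix, ".ind")
  }
  if (is.null(geno) || is.null(snp) || is.null(ind))
    stop_es("need either a prefix or all three of geno/snp/ind paths")
  ind_df <- read_ind(ind)
  snp_df <- read_snp(snp)
  n_ind <- nrow(ind_df)
  n_snp <- nrow(snp_df)
  enc <- detect_geno_encoding(geno)
  if (enc == "PACKED") {
    L <- packed_record_length(n_ind)
    con <- file(geno, "rb")
    hdr <- parse_packed_header(readBin(con, "raw", n = L))
    close(con)
    if (hdr$n_ind != n_ind || hdr$n_snp != n_snp)
      stop_es(sprintf(
        "packed header counts (%d individuals, %d SNPs) do not match metadata (%d, %d)",
        hdr$n_ind, hdr$n_snp, n_ind, n_snp))
    expected <- (n_snp + 1) * L
    if (file.size(geno) != expected)
      stop_es(sprintf("packed .geno truncated: %d bytes, expected %d",
                      file.size(geno), expected))
  } else {
    con <- file(geno, "r")
    first <- readLines(con, n = 1L)
    close(con)
    if (nchar(trimws(first, which = "right")) != n_ind)
      stop_es(sprintf("text .geno line 1 has %d genotypes but .ind lists %d individuals",
                      nchar(trimws(first, which = "right")), n_ind))
  }
  structure(list(geno_path = geno, snp_path = snp, ind_path = ind,
                 encoding = enc, n_ind = n_ind, n_snp = n_snp,
                 snp = snp_df, ind = ind_df),
            class = "es_dataset")
}

#' @export
print.es_dataset <- function(x, ...) {
  cat(sprintf("EIGENSTRAT dataset (%s genotypes): %d SNPs x %d individuals\n",
              tolower(x$encoding), x$n_snp, x$n_ind))
  cat("  geno:", x$geno_path, "\n  snp: ", x$snp_path, "\n  ind: ", x$ind_path, "\n")
  invisible(x)
}

parse_text_lines <- function(lines, n_ind, row_offset) {
  lines <- sub("[ \t\r]+$", "", lines)
  n <- length(lines)
  if (n == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = n_ind))
  nc <- nchar(lines)
  if (any(nc != n_ind)) {
    i <- which(nc != n_ind)[1]
    stop_es(sprintf("text .geno row %d has %d genotypes, expected %d",
                    row_offset + i, nc[i], n_ind))
  }
  g <- matrix(utf8ToInt(paste(lines, collapse = "")) - 48L,
              nrow = n, ncol = n_ind, byrow = TRUE)
  bad <- !(g %in% GENO_VALUES)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop_es(sprintf("invalid genotype character '%s' at .geno row %d, individual %d",
                    intToUtf8(g[i[1], i[2]] + 48L), row_offset + i[1], i[2]))
  }
  g
}

unpack_records <- function(bytes, n_rows, L, n_ind) {
  # bytes: raw vector of n_rows * L; returns n_rows x n_ind integer matrix
  nb <- ceiling(n_ind / 4)
  b <- matrix(as.integer(bytes), nrow = n_rows, ncol = L, byrow = TRUE)
  b <- b[, seq_len(nb), drop = FALSE]
  codes <- matrix(0L, nrow = n_rows, ncol = 4L * nb)
  codes[, seq(1L, by = 4L, length.out = nb)] <- b %/% 64L
  codes[, seq(2L, by = 4L, length.out = nb)] <- (b %/% 16L) %% 4L
  codes[, seq(3L, by = 4L, length.out = nb)] <- (b %/% 4L) %% 4L
  codes[, seq(4L, by = 4L, length.out = nb)] <- b %% 4L
  code_to_geno(codes[, seq_len(n_ind), drop = FALSE])
}

pack_records <- function(values, L) {
  # values: n x n_ind matrix over {0,1,2,9}; returns raw vector of n*L bytes
  n <- nrow(values)
  n_ind <- ncol(values)
  if (!all(values %in% GENO_VALUES))
    stop_es("genotype outside {0,1,2,9} cannot be packed")
  nb <- ceiling(n_ind / 4)
  codes <- matrix(3L, nrow = n, ncol = 4L * nb)  # pad bits 11 (missing)
  codes[, seq_len(n_ind)] <- geno_to_code(values)
  bytes <- codes[, seq(1L, by = 4L, length.out = nb), drop = FALSE] * 64L +
    codes[, seq(2L, by = 4L, length.out = nb), drop = FALSE] * 16L +
    codes[, seq(3L, by = 4L, length.out = nb), drop = FALSE] * 4L +
    codes[, seq(4L, by = 4L, length.out = nb), drop = FALSE]
  out <- matrix(as.raw(255L), nrow = L, ncol = n)
  out[seq_len(nb), ] <- as.raw(t(bytes))
  as.vector(out)
}

#' Iterate over genotype data in chunks
#'
#' Returns a reader function that yields successive blocks of SNP rows (a
#' list with `values`, an integer matrix over `{0,1,2,9}`, and `row_offset`,
#' the 0-based index of its first row), and `NULL` once exhausted. Works
#' identically for text and packed encodings; at most one chunk of genotype
#' data is resident at a time.
#'
#' @param handle An `es_dataset` from [es_open()].
#' @param chunk_size Maximum rows per chunk (default 1000).
#' @return A function of no arguments; call repeatedly until it returns `NULL`.
#' @export
es_chunk_reader <- function(handle, chunk_size = 1000L) {
  stopifnot(inherits(handle, "es_dataset"))
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L) stop_es("chunk_size must be >= 1")
  offset <- 0L
  n_snp <- handle$n_snp
  n_ind <- handle$n_ind
  if (handle$encoding == "TEXT") {
    con <- file(handle$geno_path, "r")
    done <- FALSE
    function() {
      if (done) return(NULL)
      if (offset >= n_snp) {
        extra <- readLines(con, n = 1L)
        close(con)
        done <<- TRUE
        if (length(extra) && nzchar(trimws(extra)))
          stop_es(sprintf("text .geno has more rows than the %d listed in .snp", n_snp))
        return(NULL)
      }
      n <- min(chunk_size, n_snp - offset)
      lines <- readLines(con, n = n)
      if (length(lines) < n) {
        close(con); done <<- TRUE
        stop_es(sprintf("text .geno ends at row %d, expected %d rows",
                        offset + length(lines), n_snp))
      }
      values <- tryCatch(parse_text_lines(lines, n_ind, offset),
                         error = function(e) {
                           close(con); done <<- TRUE
                           stop(e)
                         })
      chunk <- list(values = values, row_offset = offset)
      offset <<- offset + n
      chunk
    }
  } else {
    L <- packed_record_length(n_ind)
    con <- file(handle$geno_path, "rb")
    seek(con, where = L)  # skip header record
    done <- FALSE
    function() {
      if (done) return(NULL)
      if (offset >= n_snp) {
        close(con); done <<- TRUE
        return(NULL)
      }
      n <- min(chunk_size, n_snp - offset)
      bytes <- readBin(con, "raw", n = n * L)
      if (length(bytes) < n * L) {
        close(con); done <<- TRUE
        stop_es(sprintf("packed .geno truncated in record %d",
                        offset + length(bytes) %/% L + 1L))
      }
      chunk <- list(values = unpack_records(bytes, n, L, n_ind),
                    row_offset = offset)
      offset <<- offset + n
      chunk
    }
  }
}

#' Read the full genotype matrix
#'
#' Convenience reader that concatenates all chunks; intended for small
#' datasets and testing, not for streaming workloads.
#'
#' @inheritParams es_chunk_reader
#' @return Integer matrix (SNPs x individuals) over `{0,1,2,9}`.
#' @export
es_read_geno <- function(handle, chunk_size = 1000L) {
  rd <- es_chunk_reader(handle, chunk_size)
  parts <- list()
  while (!is.null(ch <- rd())) parts[[length(parts) + 1L]] <- ch$values
  if (!length(parts)) return(matrix(integer(0), 0L, handle$n_ind))
  do.call(rbind, parts)
}

#' Open a streaming genotype writer
#'
#' Creates a writer that appends genotype chunks to a `.geno` file in either
#' text EIGENSTRAT or packed ANCESTRYMAP encoding. For packed output a
#' header record `"GENO <n_ind> <n_snp> 0 0"` is written first and rewritten
#' on close with the final SNP count; both hash fields are written as 0, so
#' downstream ADMIXTOOLS/EIGENSOFT runs must set `hashcheck: NO`.
#'
#' @param path Output `.geno` path.
#' @param encoding `"TEXT"` or `"PACKED"`.
#' @param n_ind Number of individuals (columns) in every chunk.
#' @return A writer object with functions `write(values)` and `close()`;
#'   `close()` returns the number of SNP rows written.
#' @export
es_geno_writer <- function(path, encoding = c("TEXT", "PACKED"), n_ind) {
  encoding <- match.arg(encoding)
  n_ind <- as.integer(n_ind)
  if (is.na(n_ind) || n_ind < 1L)
    stop_es("cannot write a genotype file with no individuals")
  n_written <- 0L
  if (encoding == "TEXT") {
    con <- file(path, "w")
    list(
      write = function(values) {
        if (ncol(values) != n_ind)
          stop_es(sprintf("chunk has %d columns, writer expects %d", ncol(values), n_ind))
        if (nrow(values))
          writeLines(vapply(seq_len(nrow(values)),
                            function(i) intToUtf8(values[i, ] + 48L), ""),
                     con)
        n_written <<- n_written + nrow(values)
        invisible(NULL)
      },
      close = function() {
        close(con)
        n_written
      })
  } else {
    L <- packed_record_length(n_ind)
    write_header <- function(con, n_snp) {
      hdr <- charToRaw(sprintf("GENO %d %d 0 0", n_ind, n_snp))
      writeBin(c(hdr, rep(as.raw(0L), L - length(hdr))), con)
    }
    con <- file(path, "wb")
    write_header(con, 0L)
    list(
      write = function(values) {
        if (ncol(values) != n_ind)
          stop_es(sprintf("chunk has %d columns, writer expects %d", ncol(values), n_ind))
        if (nrow(values)) writeBin(pack_records(values, L), con)
        n_written <<- n_written + nrow(values)
        invisible(NULL)
      },
      close = function() {
        close(con)
        con2 <- file(path, "r+b")
        write_header(con2, n_written)
        close(con2)
        n_written
      })
  }
}

#' Write a complete EIGENSTRAT or ANCESTRYMAP triple
#'
#' @param values Integer genotype matrix (SNPs x individuals).
#' @param snp,ind Metadata data frames matching the matrix dimensions.
#' @param out_prefix Output prefix; `.geno`, `.snp`, `.ind` are appended.
#' @param encoding `"TEXT"` (EIGENSTRAT) or `"PACKED"` (ANCESTRYMAP).
#' @return `out_prefix`, invisibly.
#' @export
es_write <- function(values, snp, ind, out_prefix, encoding = c("TEXT", "PACKED")) {
  encoding <- match.arg(encoding)
  if (nrow(values) != nrow(snp))
    stop_es(sprintf("genotype matrix has %d rows but .snp has %d", nrow(values), nrow(snp)))
  if (ncol(values) != nrow(ind))
    stop_es(sprintf("genotype matrix has %d columns but .ind has %d", ncol(values), nrow(ind)))
  if (nrow(ind) == 0L) stop_es("cannot write a dataset with no individuals")
  w <- es_geno_writer(paste0(out_prefix, ".geno"), encoding, nrow(ind))
  w$write(values)
  w$close()
  write_snp(snp, paste0(out_prefix, ".snp"))
  write_ind(ind, paste0(out_prefix, ".ind"))
  invisible(out_prefix)
}
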