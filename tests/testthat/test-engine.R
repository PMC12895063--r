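test_that("configuration validation catches contradictions and bad bounds before I/O", {
  expect_error(es_config(prefix = "x", out = "y", min_maf = 0.6), "0, 0.5")
  expect_error(es_config(prefix = "x", out = "y", geno_threshold = 2), "0, 1")
  expect_error(es_config(prefix = "x", out = "y", min_maf = 0.3, max_maf = 0.1),
               "exceeds")
  expect_error(es_config(prefix = "x", out = "y", keep_snps = "a", remove_snps = "b"),
               "contradictory")
  expect_error(es_config(prefix = "x", out = "y", chunk_size = 0), "positive")
  expect_error(es_config(prefix = "x"), "nothing to do")
  expect_identical(es_config(prefix = "x", update_ind = "m")$mode, "UPDATE_ONLY")
  expect_identical(es_config(prefix = "x", out = "y")$mode, "PROCESSING")
  expect_error(es_config(prefix = "x", geno_threshold = 0.1), "--out")
})

test_that("a pure conversion run is a bit-exact round trip", {
  d <- tempfile(); dir.create(d)
  fx <- random_fixture(101)
  prefix <- file.path(d, "in")
  es_write(fx$values, fx$snp, fx$ind, prefix)
  run_pipeline(es_config(prefix = prefix, out = file.path(d, "packed"),
                         out_format = "ancestrymap"))
  h <- es_open(file.path(d, "packed"))
  expect_identical(h$encoding, "PACKED")
  run_pipeline(es_config(prefix = file.path(d, "packed"),
                         out = file.path(d, "back"), out_format = "eigenstrat"))
  expect_identical(readLines(file.path(d, "back.geno")),
                   readLines(paste0(prefix, ".geno")))
  expect_identical(read_snp(file.path(d, "back.snp")), fx$snp)
  expect_identical(read_ind(file.path(d, "back.ind")), fx$ind)
})

test_that("pipeline output is invariant to chunk size and identical across runs", {
  d <- tempfile(); dir.create(d)
  fx <- random_fixture(102)
  prefix <- file.path(d, "in")
  es_write(fx$values, fx$snp, fx$ind, prefix)
  keep_pop <- write_lines_tmp(unique(fx$ind$population)[1])
  outs <- lapply(c(1, 7, 13, 1000), function(cs) {
    out <- file.path(d, paste0("out", cs))
    suppressWarnings(run_pipeline(es_config(
      prefix = prefix, out = out, chunk_size = cs,
      keep_pop = keep_pop, geno_threshold = 0.8, min_maf = 0.01,
      random_haploidise = TRUE, seed = 5L, freq = TRUE, missing = TRUE,
      verbose = TRUE)))
    lapply(paste0(out, c(".geno", ".snp", ".ind", ".frq", ".imiss", ".removed.snp")),
           readLines)
  })
  for (k in 2:4) expect_identical(outs[[k]], outs[[1]])
  # determinism: re-running the same config reproduces identical bytes
  out <- file.path(d, "again")
  suppressWarnings(run_pipeline(es_config(
    prefix = prefix, out = out, chunk_size = 7,
    keep_pop = keep_pop, geno_threshold = 0.8, min_maf = 0.01,
    random_haploidise = TRUE, seed = 5L, freq = TRUE, missing = TRUE,
    verbose = TRUE)))
  expect_identical(lapply(paste0(out, c(".geno", ".snp", ".frq")), readLines),
                   outs[[1]][c(1, 2, 4)])
})

test_that("statistics see post-filtering individuals: removing one flips a MAF decision", {
  d <- tempfile(); dir.create(d)
  ind <- data.frame(sample_id = c("S1", "S2", "S3"), sex = "F",
                    population = c("P1", "P1", "P2"), stringsAsFactors = FALSE)
  snp <- data.frame(snp_id = "rs1", chrom = 1L, genetic_pos = 0,
                    physical_pos = 100, allele1 = "A", allele2 = "G",
                    stringsAsFactors = FALSE)
  # freq 1/6 with all three individuals, 0 once S3 is removed
  es_write(matrix(c(0L, 0L, 1L), 1), snp, ind, file.path(d, "in"))
  s_all <- run_pipeline(es_config(prefix = file.path(d, "in"),
                                  out = file.path(d, "all"), min_maf = 0.05))
  expect_identical(s_all$n_snp_out, 1L)
  expect_error(
    run_pipeline(es_config(prefix = file.path(d, "in"), out = file.path(d, "sub"),
                           remove_indv = write_lines_tmp("S3"), min_maf = 0.05)),
    "no SNPs remain")
})

test_that("the .frq report covers only retained individuals and pre-QC SNPs", {
  d <- tempfile(); dir.create(d)
  m <- micro_dataset()
  es_write(m$values, m$snp, m$ind, file.path(d, "in"))
  run_pipeline(es_config(prefix = file.path(d, "in"), out = file.path(d, "out"),
                         remove_pop = write_lines_tmp("P2"),
                         min_maf = 0.05, freq = TRUE))
  frq <- read.delim(file.path(d, "out.frq"))
  retained <- m$ind$population == "P1"
  ref <- ref_snp_stats(m$values[, retained], m$snp$chrom, m$ind$sex[retained])
  expect_equal(frq$freq, ref$freq)          # frequencies over the 3 kept columns
  expect_identical(nrow(frq), 10L)          # stats precede the MAF filter
})

test_that("removal reasons are logged per SNP in the documented vocabulary", {
  d <- tempfile(); dir.create(d)
  m <- micro_dataset()
  es_write(m$values, m$snp, m$ind, file.path(d, "in"))
  s <- run_pipeline(es_config(prefix = file.path(d, "in"), out = file.path(d, "out"),
                              remove_chr = "24", geno_threshold = 0.5,
                              min_maf = 0.05, verbose = TRUE))
  log <- read.delim(file.path(d, "out.removed.snp"))
  expect_identical(log$reason[log$snp_id == "rsY1"], "chromosome")
  expect_identical(log$reason[log$snp_id == "rs4"], "geno")   # all-missing row
  expect_identical(log$reason[log$snp_id == "rs2"], "min-maf")
  expect_true(all(log$reason %in% c("snp-list", "region", "chromosome", "geno",
                                    "min-maf", "max-maf", "polarize-het",
                                    "polarize-missing", "polarize-unmatched")))
  expect_identical(s$n_snp_out + nrow(log), 10L)
})

test_that("the whole pipeline agrees with the naive reference under random flag draws", {
  for (seed in 1:6) {
    d <- tempfile(); dir.create(d)
    fx <- random_fixture(200 + seed)
    prefix <- file.path(d, "in")
    es_write(fx$values, fx$snp, fx$ind, prefix)
    set.seed(300 + seed)
    opts <- list()
    args <- list(prefix = prefix, out = file.path(d, "out"),
                 chunk_size = sample(c(1, 7, 13, 1000), 1),
                 freq = TRUE, missing = TRUE)
    if (runif(1) < 0.5) {
      pop <- sample(unique(fx$ind$population), 1)
      opts$keep_pop <- pop
      args$keep_pop <- write_lines_tmp(pop)
    }
    if (runif(1) < 0.5) {
      ids <- sample(fx$snp$snp_id, nrow(fx$snp) %/% 2)
      opts$remove_snps <- ids
      args$remove_snps <- write_lines_tmp(ids)
    }
    if (runif(1) < 0.5) {
      opts$chrom_keep <- c(1L, 23L, 24L)
      args$keep_chr <- "1,X,Y"
    }
    if (runif(1) < 0.5) {
      opts$regions_remove <- data.frame(chrom = 1L, start = 1, end = 5e6)
      args$remove_region <- "1:1-5 000 000"
    }
    if (runif(1) < 0.5) opts$sex_chr_missing <- args$sex_chr_missing <- TRUE
    if (runif(1) < 0.5) {
      opts$seed <- 11
      args$random_haploidise <- TRUE
      args$seed <- 11L
    }
    if (runif(1) < 0.7) opts$geno <- args$geno_threshold <- runif(1, 0.2, 0.9)
    if (runif(1) < 0.7) opts$min_maf <- args$min_maf <- runif(1, 0.01, 0.2)
    ref <- ref_pipeline(fx$values, fx$snp, fx$ind, opts)
    if (nrow(ref$values) == 0) next  # reference predicts an empty-output error
    s <- suppressWarnings(run_pipeline(do.call(es_config, args)))
    got <- es_open(file.path(d, "out"))
    expect_identical(es_read_geno(got), ref$values)
    expect_identical(got$snp, `rownames<-`(ref$snp, NULL))
    expect_identical(got$ind, `rownames<-`(ref$ind, NULL))
    frq <- read.delim(file.path(d, "out.frq"))
    expect_equal(frq$freq, ref$frq$freq)
    expect_equal(frq$missing_rate, ref$frq$missing_rate)
    im <- read.delim(file.path(d, "out.imiss"))
    expect_equal(im$missing_rate, ref$imiss$missing_rate)
    unlink(d, recursive = TRUE)
  }
})

test_that("the command-line interface maps flags, logs, and signals usage errors", {
  d <- tempfile(); dir.create(d)
  fx <- random_fixture(400)
  prefix <- file.path(d, "in")
  es_write(fx$values, fx$snp, fx$ind, prefix)
  code <- suppressMessages(cli_main(c("--prefix", prefix, "--keep-chr", "1-22",
                                      "--out", file.path(d, "auto"))))
  expect_identical(code, 0L)
  out <- es_open(file.path(d, "auto"))
  expect_true(all(out$snp$chrom <= 22))

  expect_identical(suppressMessages(cli_main(c("--prefix", prefix,
                                               "--min-maf", "0.6",
                                               "--out", file.path(d, "x")))), 2L)
  expect_identical(suppressWarnings(suppressMessages(
    cli_main(c("--prefix", file.path(d, "absent"), "--out", file.path(d, "x"))))), 1L)
})

test_that("library functions reproduce the CLI statistics chunk by chunk", {
  d <- tempfile(); dir.create(d)
  fx <- random_fixture(401)
  prefix <- file.path(d, "in")
  es_write(fx$values, fx$snp, fx$ind, prefix)
  run_pipeline(es_config(prefix = prefix, out = file.path(d, "out"),
                         freq = TRUE, missing = TRUE))
  h <- es_open(prefix)
  acc <- ind_missing_accumulator(h$ind$sex)
  rd <- es_chunk_reader(h, 17)
  frq <- list()
  while (!is.null(ch <- rd())) {
    i <- ch$row_offset + seq_len(nrow(ch$values))
    acc$add(ch$values, h$snp$chrom[i])
    frq[[length(frq) + 1L]] <- snp_stats(ch$values, h$snp$chrom[i], h$ind$sex)
  }
  api_frq <- do.call(rbind, frq)
  cli_frq <- read.delim(file.path(d, "out.frq"))
  expect_equal(api_frq$freq, cli_frq$freq)
  cli_im <- read.delim(file.path(d, "out.imiss"))
  expect_equal(acc$result()$missing_rate, cli_im$missing_rate)
})
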