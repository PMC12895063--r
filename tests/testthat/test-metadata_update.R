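make_ind <- function() data.frame(sample_id = c("S1", "S2"),
                                  sex = c("M", "F"),
                                  population = c("P1", "P2"),
                                  stringsAsFactors = FALSE)

test_that("population relabeling matches sample IDs and reports unmatched keys", {
  u <- update_ind_pop(make_ind(), c(S1 = "Px"))
  expect_identical(u$ind$population, c("Px", "P2"))
  expect_identical(u$changed, 1L)

  u <- update_ind_pop(make_ind(), stats::setNames(character(0), character(0)))
  expect_identical(u$ind, make_ind())
  expect_identical(u$changed, 0L)

  expect_warning(u <- update_ind_pop(make_ind(), c(S9 = "Px")), "not found")
  expect_identical(u$ind, make_ind())
})

test_that("mapping files reject duplicate keys and wrong column counts", {
  expect_error(read_mapping(write_lines_tmp(c("S1 A", "S1 B"))), "S1")
  expect_error(read_mapping(write_lines_tmp("S1 A B")), "line 1")
  expect_identical(read_mapping(write_lines_tmp(c("a x", "b\ty"))),
                   c(a = "x", b = "y"))
})

test_that("SNP renaming keeps positions and refuses collisions", {
  snp <- read_snp(write_lines_tmp(c("rs1 1 0.0 1000 A G", "rs2 1 0.1 2000 C T")))
  u <- update_snp_ids(snp, c(rs1 = "chr1_1000"))
  expect_identical(u$snp$snp_id, c("chr1_1000", "rs2"))
  expect_identical(u$snp[-1], snp[-1])
  expect_identical(u$changed, 1L)

  expect_error(update_snp_ids(snp, c(rs1 = "x", rs2 = "x")), "duplicate")
  expect_identical(update_snp_ids(snp, stats::setNames(character(0), character(0)))$snp, snp)
})

test_that("genetic-map interpolation converts cM to Morgans, clamps, and hits map points", {
  snp <- data.frame(snp_id = paste0("rs", 1:4), chrom = 1L,
                    genetic_pos = 0, physical_pos = c(150, 50, 200, 300),
                    allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  map <- data.frame(chrom = 1L, physical_pos = c(100, 200), genetic_pos = c(0, 1))
  u <- interpolate_genetic_map(snp, map, "cM")
  expect_equal(u$snp$genetic_pos, c(0.005, 0, 0.01, 0.01))
  # M-unit map is taken as is
  u <- interpolate_genetic_map(snp, map, "M")
  expect_equal(u$snp$genetic_pos, c(0.5, 0, 1, 1))
})

test_that("interpolation is exact on affine maps and warns on unmapped chromosomes", {
  set.seed(5)
  a <- 1.3e-8; b <- 0.002
  pts <- sort(sample.int(1e6, 10))
  map <- data.frame(chrom = 1L, physical_pos = pts, genetic_pos = 100 * (a * pts + b))
  snp <- data.frame(snp_id = paste0("rs", 1:50), chrom = 1L, genetic_pos = 0,
                    physical_pos = sort(sample(seq(min(pts), max(pts)), 50)),
                    allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  u <- interpolate_genetic_map(snp, map, "cM")
  expect_equal(u$snp$genetic_pos, a * snp$physical_pos + b, tolerance = 1e-12)

  snp2 <- snp
  snp2$chrom[1] <- 2L
  expect_warning(u2 <- interpolate_genetic_map(snp2, map, "cM"), "absent")
  expect_identical(u2$n_unmapped, 1L)
  expect_equal(u2$snp$genetic_pos[1], 0)

  one_pt <- data.frame(chrom = 2L, physical_pos = 10, genetic_pos = 0)
  expect_error(interpolate_genetic_map(snp2, rbind(map, one_pt), "cM"),
               "fewer than 2")
})

test_that("genetic-map files skip a header line and sort by position", {
  f <- write_lines_tmp(c("chrom pos cM", "1 200 1.0", "1 100 0.0"))
  map <- read_genetic_map(f)
  expect_identical(map$physical_pos, c(100, 200))
})

test_that("strand flipping complements listed ACGT alleles and is an involution", {
  snp <- read_snp(write_lines_tmp(c("rs1 1 0 1 A G", "rs2 1 0 2 T C", "rs3 1 0 3 A 0")))
  u <- flip_strand(snp, c("rs1"))
  expect_identical(c(u$snp$allele1[1], u$snp$allele2[1]), c("T", "C"))
  expect_identical(u$snp[2:3, ], snp[2:3, ])
  twice <- flip_strand(flip_strand(snp, "rs2")$snp, "rs2")$snp
  expect_identical(twice, snp)
  expect_warning(u <- flip_strand(snp, "rs3"), "non-ACGT")
  expect_identical(u$snp, snp)
  expect_identical(u$skipped, 1L)
})

test_that("update-only mode edits in place with byte-restorable backups", {
  d <- tempfile(); dir.create(d)
  m <- micro_dataset()
  prefix <- file.path(d, "data")
  es_write(m$values, m$snp, m$ind, prefix)
  geno_before <- file.mtime(paste0(prefix, ".geno"))
  ind_orig <- readLines(paste0(prefix, ".ind"))

  mapfile <- write_lines_tmp("S1 NewPop")
  s <- run_pipeline(es_config(prefix = prefix, update_ind = mapfile))
  expect_identical(s$mode, "UPDATE_ONLY")
  expect_true(file.exists(paste0(prefix, ".ind.backup")))
  expect_identical(readLines(paste0(prefix, ".ind.backup")), ind_orig)
  expect_identical(read_ind(paste0(prefix, ".ind"))$population[1], "NewPop")
  expect_false(file.exists(paste0(prefix, ".snp.backup")))
  expect_identical(file.mtime(paste0(prefix, ".geno")), geno_before)

  # restoring the backup reproduces the original bytes
  expect_identical(readLines(paste0(prefix, ".ind.backup")), ind_orig)
  # a second in-place update refuses to clobber the existing backup
  expect_error(run_pipeline(es_config(prefix = prefix, update_ind = mapfile)),
               "backup")
})

test_that("updates combined with --out leave originals byte-identical", {
  d <- tempfile(); dir.create(d)
  m <- micro_dataset()
  prefix <- file.path(d, "data")
  es_write(m$values, m$snp, m$ind, prefix)
  orig <- lapply(paste0(prefix, c(".geno", ".snp", ".ind")), readLines)

  mapfile <- write_lines_tmp("S1 NewPop")
  s <- run_pipeline(es_config(prefix = prefix, update_ind = mapfile,
                              out = file.path(d, "out")))
  expect_identical(s$mode, "PROCESSING")
  expect_identical(lapply(paste0(prefix, c(".geno", ".snp", ".ind")), readLines), orig)
  expect_false(any(file.exists(paste0(prefix, c(".ind.backup", ".snp.backup")))))
  expect_identical(read_ind(file.path(d, "out.ind"))$population[1], "NewPop")
  expect_identical(es_read_geno(es_open(file.path(d, "out"))), m$values)
})

test_that("an update flag plus a processing flag enters processing mode", {
  d <- tempfile(); dir.create(d)
  m <- micro_dataset()
  prefix <- file.path(d, "data")
  es_write(m$values, m$snp, m$ind, prefix)
  cfg <- es_config(prefix = prefix, update_ind = write_lines_tmp("S1 NewPop"),
                   geno_threshold = 0.5, out = file.path(d, "out"))
  expect_identical(cfg$mode, "PROCESSING")
  run_pipeline(cfg)
  expect_identical(read_ind(paste0(prefix, ".ind")), m$ind)  # untouched
})
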