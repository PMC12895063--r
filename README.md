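# eigenstratr

Chunked processing of EIGENSTRAT and packed ANCESTRYMAP genotype data in R.

Ancient-DNA population genetics runs on the EIGENSTRAT triple — a genotype
file (`.geno`, one row per SNP, one character per individual, `0/1/2`
counting copies of the first allele and `9` for missing), a SNP file
(`.snp`: ID, chromosome, genetic position in Morgans, physical position,
two alleles) and an individual file (`.ind`: sample ID, sex `M/F/U`,
population label). These files feed PCA, *f*-statistics and
qpWave/qpAdm-style modelling, but the classic tooling around them loads the
whole genotype matrix into memory and offers little filtering, so routine
quality control turns into format-conversion detours.

`eigenstratr` is a library plus a command-line tool that reads, filters,
transforms, summarizes and converts these datasets by **streaming the
genotype matrix in chunks of SNP rows** (default 1000), so memory use is
bounded by one chunk plus metadata regardless of dataset size. It supports:

- text EIGENSTRAT and packed-binary ANCESTRYMAP genotypes, auto-detected,
  with bit-exact conversion in both directions;
- keep/remove filtering of individuals and populations, and SNP selection
  by ID list, genomic region (interval files, BED, or inline
  `1:1 000 000–2 000 000` specs) or chromosome spec (`1,2,5-6,22`, `chrX`);
- per-SNP allele frequency / minor allele frequency (MAF) / missingness and
  per-individual missingness, with sex-aware denominators (Y statistics
  over males only; X statistics over everyone), written as `.frq` /
  `.imiss` tables;
- missing-rate (`--geno`) and MAF (`--min-maf`, `--max-maf`) filters;
- random pseudo-haploidization (heterozygous calls resolved to a random
  homozygote — the standard representation for low-coverage ancient DNA)
  and ancestral/derived allele polarization from an ancestral-allele file
  or a reference individual;
- in-place metadata updates (population relabeling, SNP renaming,
  genetic-map re-interpolation, strand flipping) with automatic `.backup`
  copies;
- a synthetic-data generator that produces valid datasets with known truth
  tables for testing.

For each SNP with `k` copies of the first allele among `n` non-missing
genotypes of the considered individuals, the reported statistics are
`freq = k / 2n`, `MAF = min(k, 2n − k) / 2n` and
`missing rate = (n_considered − n) / n_considered`. A SNP is removed when
its missing rate exceeds `--geno` (strictly) or its MAF falls outside the
inclusive `[--min-maf, --max-maf]` band — the PLINK conventions.

Operations always run in a fixed order — metadata updates, polarization,
haploidization, individual/population filtering, sex-chromosome handling,
SNP selection, region/chromosome filtering, statistics, then
missing-rate/MAF filtering — so frequencies are never computed over
individuals that are being removed.

## Worked example

```r
library(eigenstratr)
d <- tempdir()

# a 20-individual, 120-SNP synthetic dataset (100 autosomal, 10 X, 10 Y)
generate_fixture(fixture_spec(seed = 1L), file.path(d, "demo"))

# autosomes only, drop SNPs with >50% missingness or MAF < 5%
s <- run_pipeline(es_config(
  prefix = file.path(d, "demo"), out = file.path(d, "demo_qc"),
  keep_chr = "1-22", geno_threshold = 0.5, min_maf = 0.05,
  freq = TRUE, missing = TRUE, verbose = TRUE))
print(s)
#> individuals: 20 in, 20 out
#> SNPs:        120 in, 86 out
#> SNPs removed by reason:
#>   chromosome           20
#>   min-maf              14

head(read.delim(file.path(d, "demo_qc.frq")), 3)
#>    snp_id chrom     pos allele1 allele2 n_obs      freq       maf missing_rate
#> 1 rs00001     1  794408       C       G    17 0.3529412 0.3529412         0.15
#> 2 rs00002     1 1292665       G       T    19 0.4210526 0.4210526         0.05
#> 3 rs00003     1 1579383       C       T    17 0.4117647 0.4117647         0.15
```

The 20 X/Y SNPs fall to the chromosome filter; 14 autosomal SNPs fall below
the 5% MAF bound; frequencies in `.frq` are computed over the retained
individuals only. The same run from a shell:

```sh
exec/eigenstratr --prefix demo --out demo_qc --keep-chr 1-22 \
    --geno 0.5 --min-maf 0.05 --freq --missing --verbose
```

Streaming through the library API, e.g. a per-population allele-frequency
table without ever holding the full matrix:

```r
h <- es_open(file.path(d, "demo"))
rd <- es_chunk_reader(h, chunk_size = 1000)
pops <- split(seq_len(h$n_ind), h$ind$population)
while (!is.null(ch <- rd())) {
  rows <- ch$row_offset + seq_len(nrow(ch$values))
  for (p in names(pops))
    print(head(snp_stats(ch$values[, pops[[p]], drop = FALSE],
                         h$snp$chrom[rows], h$ind$sex[pops[[p]]])$freq))
}
```

Packed ANCESTRYMAP output (`--out-format ancestrymap`) carries a zero in
the header's hash fields; set `hashcheck: NO` in ADMIXTOOLS/EIGENSOFT
parameter files when consuming such files.

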