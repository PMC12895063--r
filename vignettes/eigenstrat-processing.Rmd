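---
title: "Chunked EIGENSTRAT processing: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunked EIGENSTRAT processing: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenstratr)
```

## The processing model

`eigenstratr` treats an EIGENSTRAT dataset as a SNP-by-individual matrix
over `{0, 1, 2, 9}` (copies of the first `.snp` allele; `9` missing) that
is never materialized whole. Genotypes are streamed in chunks of SNP rows;
every operation is either *global metadata* (computed once from `.ind` /
`.snp`, held in memory — O(n_ind + n_snp)) or *per-chunk* (a pure function
of one chunk plus that metadata). The peak resident genotype data is one
chunk. This is a real contract, not an aspiration: the chunk reader is the
only access path the pipeline has, and the test suite checks that outputs
are byte-identical for chunk sizes 1, 7, 13 and 1000, which fails for any
operation that accidentally depends on chunk boundaries.

The pipeline applies operations in a fixed order:

1. metadata updates (relabeling, renaming, genetic map, strand flip)
2. allele polarization
3. random pseudo-haploidization
4. individual/population filtering (global column mask)
5. sex-chromosome handling (`--sex-chr-missing`, `--ignore-sex`,
   `--ignore-unknown`)
6. SNP-ID selection
7. region/chromosome filtering
8. `.frq` / `.imiss` statistics
9. missing-rate filter, then MAF filter

Subsetting precedes calculation, so a frequency can never include an
individual that the same run removes — the classic error this ordering
exists to prevent. A corollary worth knowing: the `.frq` and `.imiss`
tables describe the dataset *after* selection (steps 4–7) but *before* the
quality filters of step 9, because that is where the statistics step sits.
A SNP can therefore appear in `.frq` and still be absent from the output
triple, with its reason in `.removed.snp`.

Two-step filtering of individuals by their own missingness is deliberate:
run once with `--missing`, threshold the `.imiss` table, and feed the
resulting ID list to `--remove-indv` in a second run. No single flag does
both, because the denominator of the second step would be ambiguous.

## File formats

Text `.geno` rows must contain exactly one character per individual.
`.ind` and `.snp` are whitespace-delimited (any mix of spaces and tabs on
read, single spaces on write, which all EIGENSTRAT consumers accept).
Four-column `.snp` files without alleles are rejected: strand flipping and
polarization are meaningless without alleles, and accepting such files
would make half the tool silently inapplicable.

Packed ANCESTRYMAP `.geno` files have one record of
`L = max(ceil(n_ind / 4), 48)` bytes per SNP plus a header record
`"GENO <n_ind> <n_snp> <hash> <hash>"` null-padded to `L`. Genotypes pack
two bits per individual, most significant pair first
(`0→00, 1→01, 2→10, 9→11`); pad bits are written as `11` (missing) so a
truncated or re-dimensioned file reads as missing rather than as phantom
homozygotes. The header hash is written as `0`: the legacy hash algorithm
is undocumented, so files produced here require `hashcheck: NO` downstream
(the CLI prints this reminder after every packed write). When output SNPs
are filtered, the final SNP count is only known after the last chunk, so
the header is written with a placeholder and rewritten in place on close.

## Statistics and their denominators

For each SNP, with `k` copies of allele 1 among `n` non-missing genotypes
of the *considered* individuals: `freq = k/2n`, `MAF = min(k, 2n−k)/2n`,
`missing = (n_considered − n)/n_considered`. Considered means: all
retained individuals for autosomes and X; males only for Y. Females should
not carry Y variants, so including them would dilute Y missingness with
structural zeros; X is kept all-individual because both sexes carry X.
Symmetrically, per-individual missing rates exclude Y SNPs from the
denominator of non-male individuals — otherwise every female would carry
an apparent missingness floor proportional to the Y SNP count. The per-SNP
rule is the established one; the per-individual mirror is this package's
choice and is documented here precisely because other tools differ.

Pseudo-haploid data are diploid-coded (`0/2`), and the frequency
denominator stays `2n` on all chromosomes: frequencies remain correct
because both the numerator and denominator double together.

Two flags adjust the denominators. `--ignore-sex` treats every SNP
autosomally (useful when `.ind` sex codes are unreliable);
`--ignore-unknown` removes sex-`U` individuals from X and Y denominators
(on Y they are already excluded). These semantics are this package's
interpretation of the flag names, and are stated here rather than assumed
familiar.

`--sex-chr-missing` rewrites genotypes (not just denominators): Y calls of
non-male individuals and heterozygous X calls of males become `9`, since
both are biologically impossible and usually indicate contamination or
mapping artifacts.

Filter conventions are PLINK's: the missing-rate filter removes strictly
above the threshold (`--geno 0.1` keeps a SNP at exactly 0.1), MAF bounds
are inclusive, and an all-missing SNP has undefined frequency (reported
`NA`) but is treated as MAF 0 so that any positive `--min-maf` removes it.

A numerical detail that matters at boundaries: MAF is computed from allele
counts as `min(k, 2n−k)/2n`, not as `min(f, 1−f)`. In doubles,
`1 − 5/6 < 1/6` by one ulp, so the count form is what makes "MAF exactly
at the bound is kept" actually true.

## Transforms

**Pseudo-haploidization** replaces every heterozygous call by `0` or `2`
with probability one half. Draws are keyed to the absolute SNP row and the
individual column: one sub-seed per row is derived from the master seed up
front, and each row draws a full vector of uniforms, one per column. This
costs a few wasted draws but buys two invariances the tests rely on — the
result is identical for every chunk size, and resolving one extra
individual cannot shift the draws of the others. The master seed defaults
to 42 and is logged on every run.

**Polarization** re-orients each SNP so allele 1 is ancestral. The
ancestral state comes from a two-column file (SNP ID, ancestral allele) or
from a reference individual in the dataset whose column is extracted in a
prior streaming pass; a file path selects file mode, anything else is
taken as a sample ID. Where the ancestral allele equals allele 2, alleles
are swapped and genotypes recoded `g → 2−g`; frequencies map to their
complement and MAF is unchanged (tested exactly). SNPs whose ancestral
state cannot be determined — reference heterozygous or missing, ID absent
from the file, or a character matching neither allele — are dropped with a
logged reason, because a mixed-orientation output silently corrupts
derived-allele analyses downstream. Matching is case-insensitive;
complementary-strand ancestral alleles are *not* auto-resolved (run
`--flip-strand` first), since auto-resolution would mask strand errors at
A/T and C/G SNPs. The reference individual stays in the output; removing
it implicitly would change individual counts behind the user's back.

## Metadata updates

Update-only mode (update flags, no `--out`, no processing flags) rewrites
`.ind`/`.snp` in place after copying the original to `<name>.backup`, and
never touches `.geno`. An existing `.backup` aborts the run rather than
being overwritten — the oldest recoverable state wins. Combined with
`--out` or any processing flag, updates flow into the new outputs and the
inputs stay byte-identical.

Genetic-map files are whitespace-delimited (chromosome, physical bp,
genetic position), with an auto-skipped header. `--map-unit` gives the
unit of the *map file* (default cM, divided by 100 on read); the `.snp`
genetic column is always written in Morgans, its conventional unit. SNPs
outside the map range are clamped to the end values rather than
extrapolated — extrapolation can produce negative genetic distances.
Chromosomes absent from the map leave their SNPs unchanged with a warning,
which is the safe behavior for deliberately partial maps; a chromosome
with fewer than two map points is an error because interpolation is
undefined. Interpolation is linear and exact on affine maps to machine
precision (tested).

## Selection semantics

Population-level keep/remove is applied before individual-level, so
`--keep-pop P1 --remove-indv S1` means "population P1 except S1".
Simultaneous keep and remove of the same kind is refused as contradictory
rather than given an arbitrary precedence. IDs in lists that do not occur
in the dataset warn but do not fail, so panel supersets can be used as-is.

Regions are 1-based inclusive, matching the inline `CHR:START-END` style
(digits may contain spaces or commas; hyphen and en-dash both work), with
one exception: files ending in `.bed` are converted from BED's 0-based
half-open convention. Chromosome specs accept sets and ranges with or
without a `chr` prefix; `X`/`Y` map to the configured `--sex-chr` codes
(default 23, 24). Point-in-interval queries go through an IRanges interval
index, and a property test checks the index against a brute-force scan.

## The synthetic-data generator

`generate_fixture()` draws per-SNP allele frequencies from a Beta
distribution (default Beta(0.8, 0.8), a U-shaped spectrum with common rare
variants), genotypes as binomial(2, f), and missingness as a per-SNP rate
(uniform on [0, 0.3] by default, the typical range after ancient-DNA
capture) scaled by a per-individual inflation factor (uniform on [0.5, 2])
that emulates variable sample quality. Defaults are 20 individuals and 120
SNPs across two autosomes plus X and Y. Alongside the triple it writes
truth tables computed by plain elementwise loops that share no code with
the streaming implementation — an independent enumeration oracle.

What the generator does *not* emulate: linkage disequilibrium, population
structure in the frequencies, reference bias, or damage-driven genotype
errors. No operation in this package depends on any of those, so passing
tests certify format handling, bookkeeping and arithmetic — not inference
quality on real ancient DNA.

`micro_dataset()` is a fixed 6-individual × 10-SNP dataset with
hand-placed heterozygotes, an all-missing SNP, a monomorphic SNP, female Y
calls, male X heterozygotes, and one SNP at exactly MAF 1/6 to pin the
inclusive filter boundary. With 12 alleles the MAF grid is k/12, so 1/6 is
the finest boundary such a dataset can realize exactly.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run on simulated datasets of up
to 50 individuals × ~500 SNPs (100 datasets for round-trip checks, 20 for
chunk-size sweeps, one 100 × 500 dataset giving >20 000 heterozygotes for
the haploidization law), sizes at which the whole-matrix reference
implementation used as an oracle stays trivially checkable. Identical
configuration and seed give byte-identical outputs; all randomness flows
from the single `--seed`.

## Known limitations

- The transposed binary variant of the format (individual-by-SNP records)
  is not read or written.
- Packed headers carry a zero hash; downstream tools must disable hash
  checking.
- No multithreading: the streaming design targets memory, not CPU
  parallelism.
- Merging multiple datasets is out of scope; the tool processes one triple
  per run.
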