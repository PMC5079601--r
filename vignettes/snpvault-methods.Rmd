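---
title: "snpvault: compressed genotype storage and set-based subset management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snpvault: compressed genotype storage and set-based subset management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpvault)
```

## The problem

High-throughput SNP genotyping produces data faster than most groups can
manage it. Two habits make it worse: storing genotypes one row per SNP in a
relational database (a single 96-well plate on an 800K array already needs
`eavRowCount(96, 800000)` = 76.8 million rows), and filtering PLINK files on
disk, which leaves a trail of near-identical ped/ped/ped copies whose
provenance nobody remembers. snpvault is a repository, not an analysis tool:
it stores biallelic genotypes losslessly at 2 bits each, records every
derived subset as a *named genotype set* with full lineage, and exports any
set back to PLINK ped/map (or a compact "0125" digit format) fast enough
that the working style can be *export, analyze, delete*.

## The storage model

A **panel** is an ordered SNP map; position $i$ of every genotype record on
that panel is the panel's $i$-th SNP, so per-genotype annotation costs
nothing. A biallelic genotype has four states — homozygous for allele 1,
heterozygous, no-call, homozygous for allele 2 — encoded as integers
0/1/2/3 in two bits. Code $i$ (1-based) occupies bits
$2((i-1) \bmod 4)$ and $2((i-1)\bmod 4)+1$ of payload byte
$\lfloor (i-1)/4\rfloor$, least-significant bits first, pad bits zero. The
layout is a package contract (the two-bit fields could equally have been
laid out MSB-first; a fixed documented order makes payloads byte-exact and
testable), giving

* `packedSize(n)` $= \lceil n/4 \rceil$ bytes per record — an 800K record is
  1,600,000 bits;
* `snpCapacity(b)` $= 4b$ — four million genotypes per decimal megabyte.

A **genotype set** is a named pair of selection vectors: a SNP selection
(one bit per panel position, `selectionBytes(n)` $= \lceil n/8\rceil$ bytes)
and an individual selection (an ordered list of internal record keys, four
bytes each). Creating a subset therefore stores kilobytes regardless of how
many gigabytes the genotypes occupy, and the genotype payload is never
copied. Individual selections hold *record* keys rather than individual
keys: a re-genotyped sample has several records under one sample ID, and a
selection must say which physical record it means — this is also what makes
duplicate handling and export unambiguous.

The store itself is a set of normalized, timestamped tables (panels, SNP
maps, individuals, genotype records, both selection kinds, genotype sets,
phenotypes, comments) held behind a handle with reference semantics and
serialized to a single backing file. The relational layer is implemented in
the package; it enforces referential integrity on every operation
(`validateStore()` is a full-scan check used heavily in the tests) and
performs cascading deletes along the dependency graph, refusing to drop a
selection that sets still reference unless asked to cascade.

## Import, coding and losslessness

Maps are imported before data (`importPanel()`), and every data import
(`importData()`) must present its map again; the map is checked for
identity with the stored panel on SNP name, chromosome and position, in
order. cM values are ignored — they carry no information the store uses.
Any biallelic labeling (A/B, A/C/G/T) is supported. When the map carries an
allele-coding column it fixes which homozygote is code 0; when it does not,
the coding is inferred from the ped in first-observed order (a heterozygote
discovering both alleles at once is ordered lexicographically) and
persisted, so later imports and all exports are stable. Monomorphic SNPs
record the placeholder "0" as their second allele; a conflicting allele in a
later import is an error, never a silent reassignment. Imports are atomic —
any parse or encoding error aborts before the store is touched.

Exports decode through the persisted coding, emitting heterozygotes in the
canonical (allele1, allele2) order; since ped heterozygotes are unordered,
an import–export cycle reproduces the input file exactly (byte-identical in
the suite's fixtures, which are generated in canonical order). Exported
maps are plain 4-column PLINK with cM 0. The "0125" format writes one digit
per genotype — 0, 1, 2 for the called states and 5 for missing — one
tab-separated line per sample.

The export loop is the package's performance core: one payload fetch per
sample, then a bulk unpack of exactly the positions flagged in the SNP
selection (mask/shift over the payload bytes in C++), independent of panel
size. Pack, unpack and the per-SNP counting scans are the only compiled
code; everything else is plain R over the normalized tables.

## Filters and their exact definitions

Each subset operation reads one parent set and creates one new named set;
a dimension the operation does not touch is *inherited by reference* (the
new set points at the parent's selection), which is why a duplicate-removal
set reuses the import's full SNP selection unchanged. Provenance is a
parent pointer plus a human-readable Source string per selection;
`provenanceReport()` prints sets indented by derivation depth.

* **Duplicates** (`removeDuplicates`): a duplicate is the same external
  sample ID with more than one genotype record *on the same panel*;
  repeats across panels are legitimate multi-panel genotyping. The
  surviving record is the one with the earliest insertion timestamp (ties
  by record key) — stable and deterministic.
* **Chromosomes** (`filterChromosomes`): bits of SNPs on the excluded
  (textual) labels are zeroed; unknown labels warn rather than error.
* **No-call** (`filterNocall`): samples first — each sample's no-call
  frequency over the parent's *active* SNPs, dropped when strictly above
  the sample threshold — then SNPs, with frequencies over the *retained*
  samples, zeroed when strictly above the SNP threshold. The order
  matters and is fixed; both stages in one call mirror the one-command
  usage the workflow expects.
* **MAF** (`filterMaf`): per active SNP, the allele-1 frequency over called
  genotypes is $(2n_0 + n_1) / (2(n_0+n_1+n_3))$; SNPs whose minor allele
  frequency falls strictly below the floor are zeroed. An all-missing SNP
  has no defined MAF and fails any floor above zero (and, having no-call
  frequency 1, also any no-call threshold below 1). A floor of 0 removes
  nothing. Because removals at a higher floor contain removals at a lower
  one, chained floors (0.03 then 0.05) equal the higher floor applied
  directly while the sample set is unchanged — property-tested.

The threshold flag is named `maf` and is interpreted as a minor-allele
frequency floor, the standard QC meaning; dropping *common* SNPs by a
literal major-allele-frequency cutoff of 0.03 would discard essentially
everything and matches no known workflow.

All filter decisions are checked against an independent dense-matrix
implementation (plain `rowMeans`/`colMeans`/counting on the unpacked
matrix) over hundreds of random fixtures.

## Phenotypes

Phenotypes use an entity–attribute–value table keyed by external sample ID:
any number of named attributes, values stored as uninterpreted text, one
row per non-empty CSV cell. Missing cells are absent values, not empty
strings. Exporting a genotype set scans for phenotypes of its samples and
writes one CSV row per covered sample under the sorted union of attribute
names; sets without phenotype coverage produce no file. Phenotype
operations never touch genotype tables.

## The synthetic-data generator

`genMap()`/`genPed()` (and `importSimulated()`, the packed bulk-load
equivalent for panel sizes where a ped text file would be impractically
large — a 5,498-sample, 580,961-SNP ped would be ~13 GB of text) define the
data the suite runs on:

* genotypes are Hardy–Weinberg draws at a per-SNP minor allele frequency
  from a configurable sampler, default Uniform(0.05, 0.5) — a flat,
  common-variant spectrum typical of array content after design-stage
  screening;
* each genotype is independently missing with probability `nocallRate`,
  default 0.01, a typical array-wide missingness;
* duplicate IDs are genuine re-genotypings: fresh draws under a repeated
  sample ID;
* everything is deterministic under a seed, byte-identical files included.

What this emulates is the *management* workload: volumes, duplicates,
missingness, per-SNP frequencies. What it does not emulate is population
structure, linkage disequilibrium, batch effects or genotyping-error
correlation — so passing tests certify storage, filtering arithmetic and
round-trip fidelity, not biological realism of downstream analyses. With
independent uniform missingness the no-call filters at 0.05/0.03 remove
little or nothing at large sample sizes (frequencies concentrate tightly
around 0.01); the correctness of the filters is therefore established on
small adversarial fixtures and random dense matrices, while the full-scale
run establishes scale, provenance and monotonicity.

## Problem sizes and numerical choices

The suite exercises, as its standard scales: a 500-sample × 10,000-SNP
ped/map round trip; 200 random ≤50×200 matrices for filter–oracle
agreement; and one full-scale workflow on a 580,961-SNP panel (14 SNPs on
chromosome W) with 5,498 records including 11 duplicate IDs — duplicate
removal, W exclusion, no-call filtering at 0.05/0.03, then MAF floors 0.03
and 0.05 chained, reproducing the panel's published subset counts (5,487
samples; 580,947 SNPs). These sizes keep the whole suite within a few
minutes on one CPU while still running the method at the scale its design
targets.

Zero-cost subsetting is demonstrated two ways: any filter chain changes the
genotype payload byte count by exactly zero, and one hundred list-based
cohort subsets (25 samples each, SNP selection shared by reference) add
selection storage below 1% of the payload. The second figure is
workload-dependent by nature: a filter that modifies the SNP selection
stores a fresh bit vector (⌈n/8⌉ bytes), so a hundred *SNP-filter* sets on
a small panel would cost ~10% of a 1.25 MB payload, while on the 580,961-SNP
panel the same hundred sets cost well under 1% of its 0.8 GB. The
sample-list workload is the one the set concept is designed for — many
per-cohort views over one shared panel selection.

Throughput is reported, never asserted absolutely — wall-clock rates are
hardware-bound. Two scale relations are asserted because they follow from
the design rather than the machine: exporting a chromosome subset takes
less wall time than exporting its full parent at equal sample count (the
selection scan is the same; decoding and output shrink), and the per-SNP
import rate of a 100K panel is within a factor of 3 of a 10K panel at equal
total genotypes (per-record overhead is small against per-SNP encode+pack
work; the timed import section deliberately includes packing, as a text
import would).

## Degenerate inputs and tie-breaks collected

* Empty map, empty ped, empty selection lists: errors, never empty objects.
* A subset whose sample or SNP selection would come out empty: refused.
* Deleting an individual prunes its records from individual selections; a
  set whose selection empties is kept but refuses to export, naming itself.
* Heterozygote input order is ignored; output order is canonical.
* Selection names `gs_/is_/ss_NNN` are zero-padded sequential counters that
  widen past 999.
* Positions in the R API are 1-based (vector indices, `unpackCodes()`
  positions); the packed layout itself is documented 0-based from the byte
  perspective.

## Known limitations

Multi-allelic sites, phased genotypes and dosage values are out of scope —
the 2-bit state space is the design. Genotype sets cannot span panels, and
no set algebra (union/intersection across sets) is provided. VCF and binary
PLINK are not read or written. The store is single-user and embedded; there
is no concurrent access control. Cross-platform SNP-name normalization is
explicitly not attempted: imports are trusted to present compatible
ped/map pairs, and the map-identity check is the only guard.
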