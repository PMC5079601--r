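# snpvault

Compressed storage and set-based management of large-scale biallelic SNP
genotype data.

Groups running genotyping programs — animal and plant breeding, human
cohorts — accumulate PLINK ped/map deliveries by the plate and then filter
them into a sprawl of near-identical file copies. The two standard pains
are storage (a relational "one row per SNP" design needs 96 × 800,000 =
76.8 million rows for a single 96-well plate on an 800K array) and
provenance (which `final_qc_v3.ped` came from what?). snpvault is a
repository for this workload, not an analysis tool: it stores genotypes
losslessly at 2 bits each, defines subsets as named, zero-copy *genotype
sets* with recorded lineage, and exports any set back to PLINK for analysis
with the tools of your choice — supporting an export → analyze → delete
working style.

## The model

A biallelic genotype has four states, encoded in two bits:

| code | meaning                | ped tokens | "0125" digit |
|------|------------------------|------------|--------------|
| 0    | homozygous allele 1    | `A A`      | `0`          |
| 1    | heterozygous           | `A B`      | `1`          |
| 2    | no-call                | `0 0`      | `5`          |
| 3    | homozygous allele 2    | `B B`      | `2`          |

One sample's genotypes on a panel of *n* SNPs form a packed vector of
⌈*n*/4⌉ bytes (code *i* sits in bits 2((*i*−1) mod 4)..+1 of byte
⌊(*i*−1)/4⌋, LSB-first): an 800K record is 1.6 million bits, and a
megabyte holds four million genotypes. The SNP map (panel) is stored once;
vector position identifies the SNP.

A **genotype set** is a named pair (SNP selection bit vector, individual
selection key list). Subsets — from explicit sample/SNP lists or from
database-side filters — only ever create new selection vectors (kilobytes),
never genotype copies. Filters provided, with their exact definitions:

* duplicate-record removal (same sample ID, same panel; earliest record
  survives);
* chromosome exclusion (textual labels, so `W`, `X`, `MT` work);
* no-call filtering: samples whose missing fraction over active SNPs
  exceeds the sample threshold are dropped first, then SNPs by missing
  fraction over the retained samples;
* minor-allele-frequency floor: allele-1 frequency per SNP is
  (2·n₀ + n₁) / (2·(n₀ + n₁ + n₃)) over called genotypes; SNPs with
  MAF strictly below the floor are dropped.

Phenotypes attach to sample IDs through an entity–attribute–value table
(any attribute names, text values) and travel with exports as CSV.

## Worked example

```r
library(snpvault)
map <- genMap("chip.map", 8, c("1" = 6, "W" = 2), seed = 7)   # synthetic 8-SNP map
genPed("chip.ped", map, 3, nocallRate = 0.1, seed = 8)        # 3 samples

st <- initStore("cattle.db")
importPanel(st, "chip.map", "chip8")                          # map first
gs  <- importData(st, "chip.ped", "chip.map", "chip8", comment = "plate 1")
g2  <- filterChromosomes(st, gs, "W")
g3  <- filterMaf(st, g2, 0.2)
print(provenanceReport(st))
```

```
gs_001 [chip8]: is_001 + ss_001 | 3 samples, 8 SNPs
  Source: is: import chip.ped | ss: import chip.ped
  Comment: plate 1
  gs_002 [chip8]: is_001 + ss_002 | 3 samples, 6 SNPs
    Source: is: import chip.ped | ss: exclude chromosomes W on gs_001
    gs_003 [chip8]: is_001 + ss_003 | 3 samples, 4 SNPs
      Source: is: import chip.ped | ss: MAF threshold 0.2 on gs_002
```

Each row is one named set; indentation is derivation depth, the Source
column says which operation produced each selection, and the individual
selection `is_001` is shared by reference — no genotypes were copied.
Exporting the final set writes analysis-ready files:

```r
exportSet(st, g3, "plink", "qc")     # qc.ped + qc.map (4 SNPs, 3 samples)
exportSet(st, g3, "0125", "qc0125")  # one digit per genotype
```

```
$ cat qc0125.0125
S00001	1151
S00002	5010
S00003	1511
```

reading S00002's `5010`: missing at the first kept SNP, homozygous for
allele 1, heterozygous, homozygous for allele 1 — digits 0/1/2 are the
called states and 5 is missing.
`reportDatabase(st)` prints the storage ledger (here: 3
records × ⌈8/4⌉ = 6 payload bytes, 15 selection bytes).

The same workflow is available from a shell via the bundled script
(`inst/scripts/snpvault`): `snpvault init`, `panel add`, `import`,
`subset --maf 0.05 …`, `export`, `report`, `delete`, `comment` — one new
named set per subset invocation, pipeline-safe, nonzero exit on error.

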