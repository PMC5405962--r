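# suppressorSeq

Whole-genome resequencing pipeline for hunting **suppressor mutations** in
clonal bacterial isolates — with a built-in short-read simulator that
provides ground truth, so the entire analysis is testable at desk scale.

## The problem

A bacterial strain surviving on a defective or foreign essential gene
(e.g. a mutant *ftsZ*) usually owes its viability to a single spontaneous
suppressor mutation. Resequencing a panel of independently derived
suppressor strains finds it by elimination:

* variants present in **all** strains are *parental* — differences between
  the common lab parent and the public reference, irrelevant to the
  phenotype;
* a variant present in **exactly one** strain is that strain's suppressor
  candidate (*unique*);
* variants in a strict subset of strains (*shared_subset*) are not
  predicted by the single-mutation model and are flagged for review.

## The method

1. **Simulate** (or supply) a reference genome with CDS/tRNA annotation,
   per-strain genomes carrying shared + private variants, and 36-nt
   single-end reads with per-base substitution errors.
2. **Align** reads by pigeonhole seeding: a read is split into three
   disjoint 12-mers, so any placement with ≤ 2 mismatches has an exact
   seed; candidates are extended to full-length Hamming comparison. A read
   with a unique best placement is *aligned*; equally good placements at
   two or more loci make it *suppressed*; no placement within the
   two-mismatch budget makes it an *orphan*.
3. **Call SNVs** by strict consensus: at aligned depth ≥ 10, the most
   frequent base is called when it differs from the reference and is
   supported by ≥ 99 % of covering reads (at depth < 100 this is
   unanimity).
4. **Classify** calls across strains into parental / unique /
   shared_subset on exact `(position, ref, alt)` keys.
5. **Annotate** protein-level effects in resequencing-table notation
   (`L36Q`, `E38E`, `W286Stop`), subtype stop gains (TAG amber, TAA ochre,
   TGA opal), detect the tRNA anticodon change CGA→CTA that turns a strain
   into an **amber suppressor**, and mark amber stop gains in essential
   genes of suppressor strains as read through by serine
   misincorporation: `Q11Amber(S)`.

The caller has no gapped logic, so a strain whose private lesion is a
deletion shows **zero** unique calls — exactly how indel-carrying strains
present in a real point-mutation hunt.

## Worked example

Three strains on a 12-kb toy genome, noise-free reads at 25X; the shared
set contains the amber-suppressor anticodon variant, strain `sB` carries a
3-bp deletion, and strain `sC` an amber stop gain in an essential gene:

```r
library(suppressorSeq)
cfg <- PipelineConfig(
  genomeLength = 12000, geneCount = 4, trnaCount = 1, nStrains = 3,
  sharedSpec = c("anticodon", "missense", "intergenic"),
  uniqueSpec = data.frame(
    strain    = c("sA", "sB", "sC"),
    kind      = c("SNV", "DEL", "SNV"),
    effect    = c("missense", "intergenic", "stop_gain_amber"),
    essential = c(NA, NA, TRUE)),
  meanDepth = 25, errorRate = 0, seed = 11)
run <- runPipeline(cfg, verbose = FALSE)
run
#> suppressorSeq run: 3 strains on a 12000 bp reference
#>   class counts: parental = 3, unique = 2, shared_subset = 0
#>   strains with one unique call: 2 | with none: 1
#>   minimum supporting-read fraction over all calls: 1.0000
tables34(run)
#> $parental
#>   position ref alt   gene  effect n_strains
#> 1     1830   A   T gene01   H107L         3
#> 2     3500   G   T  serX1 CGA>CTA         3
#> 3     5022   C   T      -       -         3
#>
#> $unique
#>   strain position ref alt   gene      effect
#> 1     sA     1785   T   C gene01        L92P
#> 2     sC    10256   A   T gene04 L89Amber(S)
```

All three shared variants come back parental in 3/3 strains; `sA` and `sC`
each show their single unique SNV (the essential-gene amber stop in `sC`
carries the `(S)` readthrough suffix because every strain inherits the
suppressor tRNA); deletion strain `sB` shows none, and its reads falling
on the deletion junction surface as the only orphans in the run:

```r
statsTable(run)
#>    strain total_reads aligned_reads aligned_pct ... orphan_reads orphan_pct depth
#> sA     sA        8333          8333     100.00% ...            0      0.00%   25X
#> sB     sB        8331          8307      99.71% ...           24      0.29%   25X
#> sC     sC        8333          8333     100.00% ...            0      0.00%   25X
```

A thin command-line front end with `simulate` / `align` / `call` /
`classify` / `annotate` / `run` / `report` subcommands lives at
`inst/scripts/suppressorseq.R`; stages communicate through FASTA, GFF3,
FASTQ, SAM, VCF and TSV files only.

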