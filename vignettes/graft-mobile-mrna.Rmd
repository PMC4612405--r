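---
title: "Detecting graft-mobile mRNAs and estimating transmission rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting graft-mobile mRNAs and estimating transmission rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftrans)
```

## The biological question

In a grafted plant, the scion (the shoot-bearing upper partner) and the
rootstock (the root-bearing lower partner) are genetically distinct
individuals joined at the graft junction.  Messenger RNAs can cross that
junction: a transcript synthesized in one partner (the *donor*) may be
detected in the tissues of the other (the *receptor*).  Because the two
partners are different genotypes, an RNA-Seq read sampled from receptor
tissue can sometimes be assigned to its genotype of origin, turning a bulk
sequencing experiment into a genome-wide assay for mRNA movement.

`graftrans` implements that assay as a reusable, fully testable pipeline:

1. **Diagnostic SNPs.** Genomic reads of both partners are aligned to a
   common reference.  At each position the base coverage (A/C/G/T counts) is
   tallied per genotype.  A position is called homozygous when at least 7
   reads support the dominant base and the dominant base's frequency exceeds
   90%.  Positions homozygous in *both* genotypes with *different* alleles
   are diagnostic SNPs — the unit of evidence.
2. **Read classification.** An RNA-Seq read from receptor tissue is
   *donor-origin* when it aligns perfectly (zero mismatches) to the donor's
   consensus haplotype and shows the donor allele at every diagnostic locus
   it covers.
3. **Transmitting-gene calls.** A gene is called *graft transmitting* in a
   direction when its donor-origin evidence satisfies any of three rules:
   (a) one read carrying two or more diagnostic loci; (b) two or more unique
   reads covering the same locus; (c) two or more unique reads carrying
   different loci.
4. **Transmission rates.** For each diagnostic locus of a transmitting gene
   a window of one read length on either side of the locus is formed.
   Donor-origin reads inside the window are counted in the receptor and the
   donor tissue libraries, normalized to reads per million mapped reads
   (RPM), and combined as

   $$\mathrm{rate} = \frac{\mathrm{RPM}_{receptor}}
        {\mathrm{RPM}_{receptor} + \mathrm{RPM}_{donor}},$$

   the receptor share of all donor-attributable signal at that locus.  The
   gene-level rate is the unweighted mean over the gene's loci, and rates
   are flagged *reportable* only when at least 50 donor reads back them.
5. **Expression.** Gene expression is summarized as RPKM (reads per kilobase
   of exon model per million mapped reads), with an optional read-exclusion
   hook for rRNA filtering.

## A synthetic experiment end to end

The package ships a generator that emulates a grafted-plant sequencing
experiment with known ground truth, so the entire pipeline can be exercised
and validated with no external data:

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 40000, n_genes = 10, seed = 42)
sim <- simulate_graft_experiment(cfg)

res <- run_graft_pipeline(pipeline_config(
  reference = sim$pair$reference, gene_models = sim$pair$genes,
  genomic = sim$genomic, rna = sim$rna[c("scion", "rootstock")],
  tissue_genotype = c(scion = "A", rootstock = "B"),
  read_length = cfg$read_length))

res$gene_rates$rootstock_to_scion
```

All randomness derives from `seed`; two runs with the same configuration are
byte-identical, and `run_graft_pipeline` writes a manifest recording every
threshold and input checksum so a run can be reproduced exactly.

## What the generator emulates — and what it does not

The generator models the features of the real experiment that the detection
mathematics actually touches:

* two fully homozygous genotypes differing at planted biallelic SNPs on a
  shared reference (heterozygous loci never enter the method, which is why
  the simulated genotypes are homozygous everywhere);
* per-gene tissue-of-origin expression with log-normal expression weights;
* directional mixing: each transcript is routed to the partner tissue's
  library with the gene's transmission fraction — the quantity the rate
  estimator must recover;
* uniform substitution sequencing error and coordinate-level PCR
  duplication;
* single-exon, forward-strand genes, exercising the exon-length arithmetic
  of RPKM without splice-aware alignment.

Deliberately out of scope: indels and structural variants, paired-end insert
geometry, realistic quality strings, strand-specific library artifacts, and
spliced alignment.  Passing tests therefore demonstrate the correctness of
the genotyping, classification, detection and rate arithmetic under the
model's assumptions — not robustness to alignment artifacts present in real
spliced RNA-Seq data, which enter the pipeline only through whatever
upstream mapper produced the SAM input.

### Default study conditions

The generator's defaults describe a desk-scale version of a woody-plant
graft experiment and were fixed once, on biological grounds:

| parameter | default | rationale |
|---|---|---|
| `read_length` | 101 bp | standard Illumina RNA-Seq read length |
| `genomic_depth` | 30× | comfortably above the ~15× floor at which homozygous calls saturate |
| `error_rate` | 0.001 | typical Illumina substitution rate |
| `duplication_rate` | 0.05 | a modest PCR duplication level |
| `snp_density` | 2/kb, half diagnostic | interspecific crops are SNP-dense |
| `exon_length` | 1500 bp | a typical mRNA footprint |
| transmission fractions | mixture over {0, 0.001, 0.01, 0.1, 0.5}, weighted toward small values | observed rate distributions are dominated by rates below 0.01 |

## Numerical and design choices

Several points of the procedure are genuinely open; the package's choices,
and why:

* **Thresholds are read literally.**  "At least seven reads" is non-strict
  (`>= 7`); "greater than 90%" is strict (`> 0.9`).  A tie for the dominant
  base yields no call, since a tied base cannot be *the* dominant allele.
  The frequency denominator is the total pileup depth over all four bases.
* **Perfect match is tested against a consensus haplotype** — the reference
  with each genotype's homozygous calls substituted.  This keeps reads
  spanning *shared* (non-diagnostic) substitutions eligible, which a naive
  "mismatches only at diagnostic loci" rule would wrongly reject.
* **Conflicted reads** (donor allele at one locus, receptor allele at
  another) are discarded from evidence on both sides: they violate the
  perfect-match requirement for either assignment and most plausibly arise
  from chimeras or sequencing error.
* **"Unique reads"** in detection rules (b) and (c) are distinct alignment
  coordinate keys (`contig:start:strand`) — the post-deduplication notion of
  distinct molecules.
* **Duplicate removal** is applied to genomic libraries, keyed on
  (library, contig, start, strand) with the lexicographically smallest read
  id as the deterministic representative.  For RNA libraries coordinate
  dedup is available as a switch but off by default: the unique-read
  requirement of the detection rules is enforced on coordinate keys
  regardless, while the rate estimator keeps all reads.  Deeply covered
  short exons would otherwise saturate the limited space of start
  coordinates, censoring counts and biasing rates downward.
* **Window membership** defaults to *informative*: a read counts toward a
  locus' window only when it covers the locus with the donor allele (such a
  read is automatically contained in the window).  Reads not covering the
  SNP match both haplotypes and cannot be attributed to the donor.  The
  alternative — every perfect-donor read fully contained in the window —
  is exposed as `rule = "contained"`.
* **RPM denominators** are each library's total mapped reads after
  alignment filters, and the gene rate is the unweighted mean over loci.
  Windows clipped at contig edges use the clipped interval and are flagged.
* **Rates are estimated only for transmitting genes** (the detection step
  gates the rate step), and a locus with zero donor-attributable signal in
  both libraries yields no record rather than a silent zero.
* **The ≥50-donor-read floor** gates reporting and distribution summaries
  only — it never revokes a transmitting-gene call.
* **The built-in aligner** is ungapped test support: `max_edit + 1` disjoint
  exact k-mer seeds guarantee (by pigeonhole) a candidate for every
  alignment within the edit limit; candidates are verified by Hamming
  distance on both strands, and only reads with exactly one best-scoring
  location are emitted.  Defaults follow the conventional limits of 4 edits
  for ~100-bp and 6 for 151-bp reads.  Real data from a spliced mapper can
  enter via SAM instead; gapped records are dropped with a warning, so
  junction-spanning reads never contribute SNP evidence — a conservative
  divergence worth remembering with heavily spliced genes.

## Problem sizes used in validation

The shipped test-suite studies were sized to make their statistical checks
sharp while staying desk-scale: diagnostic-SNP exactness on a 100-kb genome
at 30× coverage; parameter recovery over 200 genes at ~2,500 transcript
draws per gene (guaranteeing at least 1,000 donor-tissue reads per gene even
at a transmission fraction of 0.5); and replicate-correlation studies over
150 genes.  At those sizes the rate estimator recovers planted fractions of
0.01 and larger with median relative error within 10%, replicate libraries
from one donor truth correlate above *r* = 0.9, and independent genotype
pairs show no correlation — the qualitative pattern expected when the donor
genotype, not chance, sets gene-level transmission behavior.

## Known limitations

* Genes or exon regions carrying no diagnostic SNP are invisible; detection
  sensitivity is conditional on SNP presence and on coverage, exactly as in
  the real assay.
* Rates compare RPM across tissues; differences in expression timing or
  transcript stability between donor and receptor tissue are not modeled
  and fold into the estimate.
* Single-end, ungapped evidence only; paired-end mates are treated as
  independent reads, and spliced reads contribute neither SNP evidence nor
  perfect-match support.
* Strandedness of stranded libraries is ignored during classification
  (allele evidence is strand-free).
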