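---
title: "Pooled mapping-by-sequencing of EMS mutants: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled mapping-by-sequencing of EMS mutants: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodmap)
```

## The genetic model

`nodmap` implements the computational chain of a classical forward-genetic
screen read out by pooled sequencing (bulked-segregant analysis of the
MutMap type):

1. **Mutagenesis.** EMS (ethyl methane sulfonate) alkylates guanine, so an
   EMS-mutagenized line carries genome-wide G:C&rarr;A:T transition SNPs. One
   of them -- in a recessive screen, a homozygous loss-of-function lesion --
   causes the phenotype.
2. **Backcross and selfing.** The mutant is crossed to the wild-type parent;
   the F1 is heterozygous at every induced SNP, with all mutant alleles in
   coupling on one haplotype. Selfing yields an F2 in which the recessive
   phenotype reappears in ~1/4 of plants (3:1 segregation, testable with
   `segregation_test()`).
3. **Pool selection and sequencing.** Phenotype-selected (mutant) F2 plants
   are pooled and sequenced. At each induced SNP the **SNP index** is the
   fraction of reads carrying the mutant allele -- the pool's mutant allele
   frequency.
4. **Linkage signal.** Every selected plant is homozygous mutant at the
   causal locus, so the index there is 1. At a site with recombination
   fraction $r$ from the causal locus each of a selected plant's two gametes
   carries the mutant allele with probability $1-r$, so

   $$\mathrm{E}[\text{SNP index}] = 1 - r,$$

   which decays to $1/2$ for unlinked sites. The causal gene therefore sits
   inside a *cluster* of SNPs whose indexes approach 1
   (`detect_linkage_clusters()`), and the lesion itself is found by
   annotating the cluster region's SNPs against gene models and ranking by
   effect severity (`annotate_variants()`, `rank_candidates()`).

A second, independent read-out -- targeted sequence capture of a candidate-gene
panel across a whole mutant collection -- is modelled by the
`build_profiles()` / `find_siblings()` / `group_allelic_series()` family:
mutants descending from the same M1 plant ("siblings") share their EMS SNP
fingerprint and must be counted once, after which independent lesions in the
same gene form an allelic series.

## Meiosis model

Gametes are generated under the **Haldane map function** (no crossover
interference): per chromosome the crossover count is Poisson with mean
$L/100$ Morgans and breakpoints are uniform, giving
$r(d) = (1 - e^{-2d/100})/2$ for a distance of $d$ cM (`haldane_r()`).
Haldane is the simplest standard meiosis model and nothing in the emulated
design constrains interference. Physical positions are mapped to genetic
positions by linear scaling of each chromosome to its cM length (no
recombination map is assumed; real genomes have hot and cold spots this
ignores).

## Sequencing model

Reads are sampled **at variant sites only**: per site, depth is
Poisson(`mean_depth`), each read draws one of the pool's $2n$ chromosome
copies uniformly, and with probability `error_rate` the read base is
replaced by one of the three other bases uniformly (observed alt probability
$p(1-e) + (1-p)e/3$). Full read simulation, alignment and variant calling
are deliberately out of scope: the analysis consumes allele counts, which is
exactly the information a pooled caller's AD field distills, and
`read_pool_vcf()` imports such counts from any VCF for real-data use.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `mutation_rate` | 5 /Mb | Induced SNP density. An EMS screen's realized density depends on dose; 5/Mb is a typical plant figure and is a config knob, not a measured constant. |
| `spectrum_fraction` | 1.0 | Fraction of G:C&rarr;A:T transitions; 1 is the canonical EMS spectrum. |
| `genetic_lengths` | 100 cM/chr | Toy map length per chromosome. |
| `pool_size` | 110 plants | Midpoint of the 100--120 selected F2 plants per pool in the emulated design. |
| `mean_depth` | 50x | Pooled depth; Poisson per site. |
| `error_rate` | 0 | Zero by default so a fixed pool yields an index of exactly 1; robustness runs use 0.001. |
| `min_depth` | 10 | Sites below this depth are dropped before clustering. |
| `index_threshold` | 0.95 | Operational threshold for an "index of 1" site: finite depth and nonzero error make exact 1.0 too brittle a membership rule. |
| `min_snps` | 3 | Minimum cluster size. |
| `max_gap_bp` | 2 Mb | Maximum distance between adjacent cluster members. |
| `min_jaccard` | 0.5 | Sibling similarity threshold on exact variant sets. |

## Design choices

* **Linked flanking SNPs.** `simulate_mapping_study()` places, in addition to
  the genome-wide background, six EMS SNPs in the 500-bp flanks immediately
  adjacent to the causal gene. This emulates the dense EMS lesions in the
  immediate candidate-gene neighbourhood that make the linkage cluster
  visible as a run of index-1 sites, and keeps them outside the gene body so
  the causal splice lesion is the unique most-severe candidate in the
  region. On the default toy map (5 Mb = 100 cM) these flanks span ~0.02 cM,
  i.e. essentially complete linkage; background SNPs further out (but still
  within a few cM) routinely join the detected cluster with indexes slightly
  below 1, which is why the cluster's *minimum* member index is near, but
  not always exactly, 1 while the causal site's own index is exactly 1 under
  zero error.
* **Cluster membership at 0.95.** "A cluster of SNPs with an SNP index of 1"
  is operationalized as a maximal run of sites with index &ge; 0.95. With
  depth ~50, a site whose true pool frequency is 1 has observed index
  exactly 1 under zero error, but any nonzero error rate or a single
  recombinant chromosome in the pool drops it below 1; 0.95 keeps such
  sites in the cluster without admitting unlinked ones (an unlinked site's
  index is Binomial(50, 0.5)/50 and essentially never reaches 0.95).
* **Splice sites = canonical dinucleotides.** Only the first and last 2
  intron bases (GT/AG) are flagged `splice_site`; extended splice regions
  (&plusmn;3--8 bp) are not called, though `splice_width` is configurable.
* **Codons on the assembled CDS.** Coding effects are computed by
  substituting the base in the extracted, strand-oriented CDS and comparing
  codons, never on genomic triplets, so junction-spanning codons are handled
  correctly. Protein positions are numbered from the start codon (p.
  notation, e.g. `G2E`); synonymous changes are reported as `G2G`,
  start-codon disruptions as `M1?`.
* **Severity ordering.** splice_site = nonsense = start_loss (5) > missense
  (4) > synonymous (3) > intronic (2) > intergenic (1). Candidate ranking is
  severity first, SNP index second, position third; the capture-panel
  candidate filter keeps severity &ge; 4 plus splice, formalizing the manual
  "which variation can explain the phenotype" search.
* **Single-linkage sibling closure.** Siblings share an M1 parent, so
  fingerprint sharing is transitive in expectation; groups are connected
  components over pairs with Jaccard &ge; 0.5. Groups spanning screening
  bulks are reported but flagged, since true siblings come from one bulk.
* **Yates correction off.** The segregation chi-square uses the plain
  Pearson statistic by default (a documented `correct = TRUE` switch
  exists); at the F2 sizes involved the correction is immaterial and the
  uncorrected statistic matches the textbook formula exactly.
* **Gene span classification.** Positions inside a gene span that are
  neither splice-site nor CDS are classed `intronic`; the planted toy genes
  have no UTRs, so a separate UTR class would never be exercised.

## What the synthetic data does and does not emulate

The generator reproduces the *statistical* structure the mapping analysis
relies on: the EMS transition spectrum, Mendelian segregation, Haldane
recombination, phenotype selection, and binomial read sampling. It does not
emulate repeat content, mapping artifacts, copy-number variation, calling
errors that are not i.i.d. base flips, natural background polymorphism
between the crossed lines, or phenotyping error in pool selection. Passing
tests therefore demonstrate correctness of the analysis chain under its
stated model, not robustness to every artifact of real pooled sequencing
data.

## Degenerate inputs and tie-breaks

* Empty variant lists, empty tracks and empty candidate regions propagate as
  empty results (with a warning where the emptiness signals a failed
  filter); `candidate_region()` on zero clusters is an error, since it means
  mapping failed.
* Equal clusters rank by chromosome then start position; equal-severity
  candidates rank by index then position; allelic-series variant lists are
  sorted so results are invariant to input order.
* Variants on N bases, ref/alt mismatches with the reference, and CDS
  lengths not divisible by 3 are rejected or flagged at construction time.

## Problem sizes

The packaged analyses and tests run on a 10-Mb, 2-chromosome genome with
~57 EMS variants, 1000 F2 plants and a 110-plant pool (single study:
seconds), 200 replicates for the allele-frequency law, 500 random tracks
and 500 random genes for the oracle-equivalence checks, and 100 replicates
of the full study for the recovery-rate estimate -- sizes chosen so each
statistical check has comfortable power while a full run stays in the
minutes range on a laptop.

## Known limitations

* The recessive, fully penetrant single-gene model is assumed throughout;
  dominance, incomplete penetrance and two-bulk designs (&Delta;SNP-index)
  are out of scope.
* No confidence intervals are attached to the SNP index (QTL-seq style
  sliding CIs are not implemented); detection is threshold-based.
* Indels and structural variants are not simulated or annotated.
* The GFF3 reader interprets gene/mRNA/exon/CDS features only and recomputes
  CDS phases rather than trusting them.
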