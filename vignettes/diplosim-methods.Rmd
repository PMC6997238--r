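---
title: "Simulating diploid personal genomes with diplosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diploid personal genomes with diplosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diplosim)
```

## The simulation model

A real personal genome is dominated by variants that are already catalogued:
most variants are known population variants, and most of those are common in
the individual's ancestral population. A small minority are novel mutations,
and a handful are large structural events or clinically significant alleles.
diplosim builds simulated genomes with exactly this composition, splitting
every simulated variant into one of three sources:

* **known variants**, sampled from a known-variant database and (for the
  common subset) weighted by background-population allele frequency;
* **novel variants**, generated de novo under empirical mutation laws;
* **special variants** (structural and pathogenic), drawn verbatim from
  curated databases.

Three user rates partition the haploid variant budget. The overall variation
rate `OVR` fixes the expected number of variants per reference base on one
haploid genome; `KVR` is the fraction of those that are known; `CVR` the
fraction of known variants that are common. With a reference of length
`GLN`, one haplotype therefore carries in expectation `GLN*OVR*KVR*CVR`
common variants, `GLN*OVR*KVR*(1-CVR)` rarer known variants and
`GLN*OVR*(1-KVR)` novel variants.

### Common variants: AF-corrected Bernoulli sampling

Each record of the common-variant database whose background-population
alternate allele frequency reaches the threshold `CVT` (default 0.01) is
sampled once per haplotype. Using raw allele frequencies would deliver the
database's own expectation, `ecvNum` (the sum of qualifying alt-AFs), rather
than the requested count, so the frequencies are rescaled by the *practical
AF coefficient*

$$\mathrm{paC} = \frac{GLN \cdot OVR \cdot KVR \cdot CVR}{\mathrm{ecvNum}},$$

and a record enters a haplotype with probability `min(1, paC * AF)`. The
rescaling is linear, so the *relative* occurrence probabilities of any two
common variants are preserved — an individual simulated against a European
AF tag will preferentially carry the variants that are actually common in
Europeans. Diploid contigs are sampled twice (once per haplotype), so common
variants can come out heterozygous or homozygous exactly as a
Hardy–Weinberg draw at the corrected frequency would.

Non-common known variants typically carry no usable frequency information;
each is included with the flat probability

$$\mathrm{paAF} = \frac{GLN \cdot OVR \cdot KVR \cdot (1 - CVR)}{\mathrm{varNum} - \mathrm{cvNum}},$$

where `varNum` and `cvNum` are the known and common record counts. Records
of the known database that would qualify as common are skipped there — the
common database is the only source of common variants, which lets both
database settings point at the same file.

### Novel variants: mutation laws

Novel variant positions are drawn uniformly over the genome. Draws landing
on `N` bases (unmeasured telomeric/centromeric sequence) or inside coding
intervals are discarded: coding mutation counts are controlled separately
(below), because coding and non-coding sequence do not mutate and fix at the
same rate. The draw budget is pre-inflated to compensate for the discards
and for collisions with higher-priority known variants:

$$\mathrm{pnvNum} = \left\lceil GLN \cdot OVR \cdot (1 - KVR) \cdot (1 + \mathrm{eoR})
  \cdot \frac{GLN}{GLN - \mathrm{nGLN} - \mathrm{modLen}} \right\rceil,
  \qquad \mathrm{eoR} = \frac{OVR \cdot KVR}{1 - OVR \cdot KVR}.$$

Each retained position becomes an indel with probability `NIDR` (default
0.1), otherwise an SNV. SNV alternate bases are chosen so that the
transition partner appears with probability `TiTv/(TiTv+1)` and each of the
two transversions with probability `1/(2(TiTv+1))`, realizing the configured
transition/transversion ratio (`TiTv` genome-wide, `TiTvC` in coding
regions, where purifying selection leaves a visibly higher ratio).

Indel lengths follow a truncated discrete power law,
$P(L = k) \propto k^{-\alpha}$ with $\alpha$ = `PLalpha` (default 1.8), the
long-tailed form observed for human indels. Lengths above the user cap
`NIDL` are folded back by the remainder rule `L <- L mod NIDL` (a remainder
of 0 maps to `NIDL`, since a zero-length indel is meaningless). Insertions
and deletions are equally likely, matching the near-symmetry of observed
indel length spectra. Coding indels whose length is not a multiple of three
shift the reading frame and are retained only with probability `FSR`
(default interval 0.2–0.3).

Novel variants are always heterozygous, placed on one haplotype.

### Special variants and merge priorities

Structural variants are never generated de novo — curated SV records rarely
carry exact breakpoint sequence, and realistic SVs cannot be invented from
length distributions alone. Instead the SV database is scanned, overlapping
records are grouped (connected components of the reference-footprint overlap
graph, using the `END` tag or `POS + |SVLEN|`), `SVN` groups are chosen at
random and one record is taken from each, so selected SVs never overlap each
other. Pathogenic variants are drawn uniformly from the records whose
clinical-significance tag is `Pathogenic` or `Likely_pathogenic`. Both kinds
are spiked in as heterozygous records.

When footprints from different sources collide, special variants win over
known variants, which win over novel variants; within a tier the
earlier-position variant wins and exact ties drop the later-processed
record. The merged output is therefore footprint-disjoint.

### Coding novels: a hard guarantee

`CDN` (default 200) coding novel variants are requested as an absolute
count, *additional to* the `GLN*OVR` budget. Because coding novels can be
lost to frameshift filtering, to N bases or to collisions, the count is
guaranteed by redrawing: positions are drawn uniformly over the concatenated
coding space, instantiated, checked against all accepted footprints, and
topped up until exactly `CDN` survive. The global non-coding draw is *not*
redrawn — its budget inflation `(1+eoR) * GLN/(GLN-nGLN-modLen)` exists
precisely to compensate the expected discards, keeping the expectation
calibrated without a hard count.

### Genome generation and coordinate maps

The generator applies every non-SV variant carried by a haplotype to the
reference, left to right with a running offset (footprints are disjoint, so
this is exact), and emits one FASTA per haplotype plus a block coordinate
map `(ref_start, hap_start, length)` per contig. Offsets change only at
indels; deleted reference positions belong to no block and map to `NA`. SV
records are ignored at sequence level. Males carry X on haplotype 1 and Y
on haplotype 2; females carry X on both and no Y; all other contigs
(including chrM and unplaced scaffolds) are treated as diploid.

## Parameters

| parameter | meaning | range | default |
|---|---|---|---|
| `gender` | sex-chromosome composition | male/female/any | any |
| `OVR` | variants per bp per haploid | 0–1 | 0.001 |
| `KVR` | known fraction of all variants | 0–1 | 0.9 |
| `CVR` | common fraction of known variants | 0–1 | 0.8 |
| `background_pop` | AF INFO tag | e.g. CAF, EUR_AF | CAF |
| `CDN` | novel coding variants (count) | 0–10000 | 200 |
| `NIDR` | indel fraction of novel variants | 0–1 | 0.1 |
| `NIDL` | max novel indel length (nt) | 2–200 | 50 |
| `TiTv` | non-coding Ti/Tv ratio | 1–5 | 2.0–2.1 |
| `TiTvC` | coding Ti/Tv ratio | 1–5 | 2.8–3.0 |
| `FSR` | frameshift retention rate | 0–1 | 0.2–0.3 |
| `SVN` | structural variants (count) | 0–1000 | 0 |
| `PVN` | pathogenic variants (count) | 0–1000 | 0 |
| `CVT` | common-AF threshold | 0–1 | 0.01 |
| `PLalpha` | indel-length power-law exponent | >1 | 1.8 |

Interval-typed parameters may be configured as `min,max`; the planner
resolves each to a concrete value drawn uniformly within the interval, so
repeated simulations vary realistically while staying inside the configured
envelope. Equal bounds pin a parameter exactly. `CVT` and `PLalpha` are
internal constants by nature but are exposed as overridable keys since they
are plain tunable scalars with documented defaults.

## Design choices in detail

Several points are deliberately fixed where more than one reading was
possible; they are recorded here as the package's own conventions.

* **The novel budget is per haplotype.** `OVR` is defined per haploid
  genome, and known-variant sampling meets its share of the budget on each
  haplotype by construction (each haplotype is sampled independently). Novel
  variants, being heterozygous, land on a single haplotype, so the planner
  draws `pnvNum` candidate positions *per haplotype* (two independent
  draws). With a genome-total reading, each haplotype would receive only
  half its novel share and the realized per-haploid rate would
  systematically undershoot `OVR` by `(1-KVR)/2` — a 5% bias at defaults,
  detectable far outside the Monte-Carlo error of the calibration tests.
* **Threshold boundary.** A record qualifies as common when its AF is
  `>= CVT` (boundary inclusive), so `CVT = 0` means every tagged record
  qualifies.
* **AF tag dialects.** The tag named `CAF` is parsed with the dbSNP
  convention (first value = reference AF, remainder = alt AFs); any other
  tag is read as plain alt-AF values. Multi-allelic records sum their alt
  AFs for the common/non-common decision; the emitted alternate allele is
  chosen proportionally to the per-allele AFs (first alt for non-common and
  special records).
* **Probability clipping.** When `paC * AF` exceeds 1 the inclusion
  probability is clipped at 1. If more than 1% of the total corrected mass
  is clipped, the count calibration degrades and a warning says so; this
  happens when the common database is small relative to the requested
  common count (real genome-scale databases sit comfortably in the
  unclipped regime).
* **Indel length support.** Sampling is from the discrete distribution on
  `1..10000` via a precomputed inverse CDF; beyond 10,000 nt the remainder
  rule makes the tail irrelevant at any legal `NIDL`.
* **VCF representation.** Indels are left-anchored (one anchor base before
  the event), genotypes are phased with `|`, haplotype 1 being the left
  allele and the `hap1` FASTA. Every record carries a `SRC` INFO tag naming
  its source; special records keep their original INFO with `SRC` appended.
* **Hemizygous contigs** (male X/Y) use a single Bernoulli draw and a
  single-allele genotype.
* **pgstat caches** (`<database>.pgstat`) store the scan statistics as
  plain key–value text; a cache older than its database, or a common-db
  cache computed under a different AF tag or threshold, is treated as
  absent and the database is rescanned.

## The synthetic fixture generator

`fixture_dataset()` builds a complete input set with planted ground truth:
uniform random contigs with one exact-length N run each, evenly spaced
coding intervals placed away from the N runs, SNV databases whose ref
alleles match the planted reference, an SV database with a controlled
number of overlapping pairs, and a ClinVar-style database with a chosen
class mix.

Two fixture choices matter for interpretation:

* Common-group AFs default to Uniform(0.30, 0.50) and rare AFs to
  Uniform(1e-4, 0.009). The high common range keeps the database's total AF
  mass above the requested common count at the default simulation scale, so
  corrected probabilities stay below 1 — the same regime a genome-scale
  database provides (with full dbSNP, `paC` is well below 1). Threshold
  behaviour is exercised separately with fixtures whose common AFs span
  `[1e-4, 0.5]`.
* Fixture databases contain only SNVs (plus the SV deletions); real
  databases also contain indels and multi-allelic records, which the
  scanners and samplers handle but the calibration fixtures do not need.

What passing the calibration suite on these fixtures shows is that the
sampling machinery realizes its configured rates and laws; it does not show
that real dbSNP/ClinVar inputs are modelled in every detail (no linkage
structure, no realistic AF spectrum shape, no mutation-rate heterogeneity
along the genome).

## Problem sizes and numerical tolerances

The test suite checks stochastic calibrations on sizes chosen to keep
Monte-Carlo error well below the tolerance being asserted: 10^6 draws for
the length-exponent recovery (MLE tolerance ±0.01), 10^5 draws for Ti/Tv,
indel-rate and frameshift-retention recovery, and 20 replicate simulations
on a 10 Mb, 5×10^4-variant fixture for the overall-rate calibration
(asserted within 3 standard errors of the replicate mean). Statistical
assertions use 3-sigma bands derived from exact Bernoulli/binomial algebra,
and goodness-of-fit checks use chi-square tests at α = 0.001. The
calibration equations are checked against independent arithmetic to 1e-12
relative error. All randomness flows from one master seed through derived
per-stage sub-seeds, making every pipeline output byte-reproducible.

## Known limitations

* SVs are annotated in the output VCF but never applied to the sequence.
* No linkage disequilibrium, pedigrees, somatic/subclonal fractions or
  read-level simulation.
* Novel variants are strictly heterozygous; recurrent de novo homozygosity
  is not modelled.
* The uniform position model ignores local mutation-rate variation
  (CpG effects, replication timing).
* One individual per run; population cohorts require repeated runs with
  different seeds.
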