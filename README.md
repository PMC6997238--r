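# diplosim

Simulation of diploid personal genomes from variant databases.

## The problem

Sequencing large numbers of individual genomes is costly, genomes with
extreme or fatal genotypes are nearly impossible to obtain, and privacy
rules restrict the reuse of real data — yet benchmarking variant callers,
annotation pipelines and population-genetic methods needs personal genomes
with *known* ground truth. Naive simulators that scatter random mutations
miss what makes a genome personal: most of an individual's variants are
known population variants (and most of those are common in the individual's
ancestral population), novel mutations follow characteristic laws
(transition/transversion bias, indel rarity, power-law indel lengths,
coding/non-coding asymmetry), and real genomes carry structural and
clinically significant alleles that can only come from curated databases.

diplosim builds simulated genomes with that composition. It is aimed at
developers of variant-calling and interpretation tools who need realistic,
fully reproducible truth sets with controllable population background.

## The model

The haploid variant budget `GLN * OVR` (genome length times overall
variation rate) is partitioned by the known rate `KVR` and common rate
`CVR`. Common database records whose background-population allele frequency
(INFO tag of your choice, e.g. `CAF` or `EUR_AF`) reaches the threshold
`CVT` are sampled per haplotype with probability `min(1, paC * AF)`, where
the *practical AF coefficient*

    paC = GLN * OVR * KVR * CVR / ecvNum

rescales the frequencies so the expected count matches the request while
preserving the variants' relative occurrence probabilities (`ecvNum` is the
sum of qualifying alt-allele frequencies). Non-common known records are
sampled at the flat rate
`paAF = GLN * OVR * KVR * (1 - CVR) / (varNum - cvNum)`. Novel variants are
placed uniformly (budget pre-inflated by the expected overlap rate
`eoR = OVR*KVR / (1 - OVR*KVR)` and by the invalid-genome fraction) and
instantiated under the mutation-law parameters: indel probability `NIDR`,
Ti/Tv ratios `TiTv`/`TiTvC`, discrete power-law indel lengths
`P(L=k) ∝ k^-PLalpha` capped by `NIDL` via a remainder rule, and frameshift
retention `FSR` for coding indels. Structural and pathogenic variants are
drawn from their databases (overlap-grouped SVs; `Pathogenic` /
`Likely_pathogenic` records only). Sources merge with priority
special > known > novel; the output is a phased single-sample VCF, one
FASTA per haplotype, and reference↔haplotype coordinate maps.

See `vignettes/diplosim-methods.Rmd` for the full treatment.

## Worked example

Everything runs off plain files; a synthetic dataset generator produces a
complete input set with a ready-made configuration:

```r
library(diplosim)

fx <- fixture_dataset("demo", genome_length = 1e6, n_contigs = 2,
                      n_known = 5000, common_fraction = 0.3,
                      n_svs = 30, sv_overlap_fraction = 0.2, n_pathogenic = 50,
                      config_params = list(SVN = 10, PVN = 5, gender = "female"),
                      seed = 20)
res <- pg_run_all(fx$config, "demo/sim", seed = 11)
```

which logs:

```
[diplosim] resolved parameters: gender=female OVR=0.001 KVR=0.9 CVR=0.8
[diplosim] database stats: GLN=1e+06 nGLN=10000 modLen=20000 varNum=5000 cvNum=1500 ecvNum=599.089
[diplosim] internal parameters: paC=1.20182 paAF=0.0514286 eoR=0.000900811 pnvNum=104
[diplosim] planned: 202 non-coding draws retained, 200 coding positions, 10 SVs, 5 pathogenic variants
[diplosim] simulated variants by source: common=1131 known=382 novel_coding=200 novel_noncoding=202 sv=10 pathogenic=5
[diplosim] wrote demo/sim.vcf
[diplosim] wrote sim.hap1.fa, sim.hap2.fa, sim.hap1.map.tsv, sim.hap2.map.tsv
```

Reading the numbers: the 1 Mb reference requests `1e6 * 0.001 = 1000`
variants per haploid — 720 common (`paC * ecvNum = 1.20 * 599 = 720`), 180
non-common known (`paAF` times the 3500 non-common records), and 100 novel,
plus the 200 requested coding novels and the 15 spiked special variants.
The realized VCF holds 1930 records because each haplotype is sampled
independently (a diploid record count, roughly twice the haploid target for
the known sources) and exactly the guaranteed 200 coding novels. The output
starts:

```
#CHROM  POS   ID        REF  ALT  QUAL  FILTER  INFO        FORMAT  SIMULATED
chr1    742   fx004775  C    A    .     .       SRC=KNOWN   GT      1|0
chr1    1263  fx000260  G    T    .     .       SRC=COMMON  GT      0|1
```

Every record names its source in `SRC`; genotypes are phased, haplotype 1
being the left allele and the `sim.hap1.fa` sequence. The coordinate maps
translate reference positions to haplotype positions across the
indel-induced offsets:

```
contig  ref_start  hap_start  length
chr1    1          1          48471
chr1    48473      48472      148245
```

(the first indel deleted reference base 48472, shifting everything after it
by −1). Programmatic access: `read_simulated_vcf("demo/sim.vcf")`,
`apply_variants()`, `map_coordinate()`.

A command-line wrapper is installed with the package
(`system.file("scripts", "diplosim", package = "diplosim")`), exposing the
same stages as subcommands `plan`, `simulate`, `generate`, `all` and
`fixtures`.

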