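# diplosim example configuration
#
# Flat "key = value" lines; '#' starts a comment; interval parameters are
# written "min,max"; equal bounds pin a parameter to one value. Any
# simulation parameter left out keeps its documented default.

# --- databases (required; .gz accepted for FASTA and VCF) -------------------
reference      = data/reference.fa
coding_bed     = data/coding.bed
known_vcf      = data/known.vcf
common_vcf     = data/common.vcf
sv_vcf         = data/sv.vcf
pathogenic_vcf = data/pathogenic.vcf

# --- simulation parameters ---------------------------------------------------
gender         = any          # male / female / any
OVR            = 0.001        # overall variation rate per bp per haploid
KVR            = 0.9          # known fraction of all variants
CVR            = 0.8          # common fraction of known variants
background_pop = CAF          # AF INFO tag (CAF uses the dbSNP convention)
CDN            = 200          # novel coding variants (guaranteed count)
NIDR           = 0.1          # indel fraction of novel variants
NIDL           = 50           # maximum novel indel length (nt)
TiTv           = 2.0,2.1      # non-coding Ti/Tv ratio
TiTvC          = 2.8,3.0      # coding Ti/Tv ratio
FSR            = 0.2,0.3      # frameshift retention rate
SVN            = 0            # structural variants to spike in
PVN            = 0            # pathogenic variants to spike in

# --- optional ---------------------------------------------------------------
# CVT     = 0.01              # common-variant AF threshold
# PLalpha = 1.8               # indel-length power-law exponent
# seed    = 1                 # master seed for full reproducibility
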