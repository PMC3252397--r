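# sHSPpipe

An R/Bioconductor-style package for the computational side of a
bacterial small heat-shock protein (sHSP) study: σ32 promoter
discovery, qRT-PCR relative quantification, GC-composition screening
for horizontal gene transfer, protein physicochemical
characterisation, and in-silico PCR — plus a synthetic-data generator
so the entire pipeline runs end-to-end with known ground truth and no
external downloads.

## Who this is for

Microbial genomics groups analysing heat-shock regulons — typically a
handful of HSP20-family genes in an organism such as
*Acidithiobacillus ferrooxidans* — who want the standard analyses of
such a study as tested, scriptable functions rather than a chain of
web servers.

## What it computes

**σ32 promoter scanning.** The heat-shock sigma factor σ32 binds a
bipartite promoter: a 6-bp −35 element and an 8-bp −10 element
separated by a variable spacer. From an aligned training set the
package builds one positional weight matrix per element,
`p(l,b) = (n(l,b) + c) / (N + 4c)` with pseudocount `c = 0.5`, and
scans the 200 bases upstream of each start codon, scoring every
placement with spacer lengths in the observed range:

    Ri(s) = Σ_l log2( p(l, s_l) / q(s_l) )        [bits, per site]
    Rsequence = Σ_l Σ_b p(l,b) log2( p(l,b)/q_b ) [bits, per model]

**ΔΔCt relative expression.** Livak & Schmittgen quantification with
an endogenous control (e.g. *alaS*): per replicate
`ΔCt = Ct_target − Ct_reference`, then
`ΔΔCt = mean ΔCt(treatment) − mean ΔCt(control)` and
`fold = 2^(−ΔΔCt)`; two-sided Student's t-test on the replicate ΔCt
sets; significant iff `p < 0.05` **and** `fold ≥ 2`.

**GC-composition HGT screen.** Pearson χ² (1 df) of each gene's
(GC, AT) counts against the genome-average coding GC (default 59%);
genes deviating at `p < 0.01` are flagged as candidate horizontal
acquisitions.

**Protein properties.** Average molecular weight (Expasy residue
masses + one water), theoretical pI (bisection on the Bjellqvist/
ProtParam Henderson–Hasselbalch charge model), and global pairwise
identity/similarity (Needleman–Wunsch, BLOSUM62, gap open 10 /
extend 0.5).

**In-silico PCR.** Exact-match primer-pair verification on both
strands; the amplicon length counts both primer footprints, and more
than one productive product is an error (non-specific primers).

## Worked example

The package ships a small synthetic study under `inst/extdata/`
(three sHSP-like genes with planted promoters and primer sites, a
simulated triplicate heat-shock Ct table; sequences are simulated,
not the real chromosome). One call runs every stage:

```r
library(sHSPpipe)
d <- system.file("extdata", package = "sHSPpipe")
cfg <- readPipelineConfig(file.path(d, "synthetic_config.yaml"))
keys <- c("genome", "coords", "cds", "proteins", "primers",
          "training_set", "ct_table")
cfg[keys] <- lapply(cfg[keys], function(f) file.path(d, f))
res <- runPipeline(cfg, out_dir = "demo_run")

res$pcr
#>      gene amplicon_bp expected_amplicon_bp
#>  Afe_1009          91                   91
#>  Afe_1437         118                  118
#>  Afe_2172          97                   97
```

Every primer pair yields exactly one product of the designed size
(91/118/97 bp, amplicon = both primer footprints plus the insert).

```r
res$composition[c("locus", "length_nt", "gc_percent", "chi_square",
                  "p_value", "hgt_flag")]
#>     locus length_nt gc_percent chi_square   p_value hgt_flag
#>  Afe_1009       438      49.77    15.4199 8.608e-05     TRUE
#>  Afe_1437       447      44.97    36.3921 1.614e-09     TRUE
#>  Afe_2172       405      57.28     0.4930    0.4826    FALSE
```

The two genes simulated below the 59% background GC are flagged as
candidate horizontal acquisitions at α = 0.01; the gene simulated at
the genome average is not.

```r
res$promoters[c("locus", "pos35", "seq35", "spacer_len", "seq10",
                "total_bits", "offset_from_ATG")]
#>     locus pos35  seq35 spacer_len    seq10 total_bits offset_from_ATG
#>  Afe_1009    52 CTTGAA         12 CCCCATAT     23.886            -149
#>  Afe_1437    50 CTTGAA         15 CCCCATAT     23.886            -151
#>  Afe_2172    23 CTTGAA         15 CCCCATAT     23.886            -178
```

The scanner recovers each planted −35/−10 pair (offsets are relative
to the start codon; `total_bits` is the per-site information of the
hit under the fitted 18-site model).

```r
res$expression[res$expression$condition == "hs_60min",
               c("gene", "fold_change", "p_value", "significant")]
#>      gene fold_change p_value significant
#>  Afe_1009      3.2125  0.0152        TRUE
#>  Afe_1437     39.3511  0.0000        TRUE
#>  Afe_2172      2.4224  0.0299        TRUE
```

At the simulated 60-minute heat shock all three genes pass the joint
rule (p < 0.05 and fold ≥ 2); the estimated folds sit near the
configured truth (3.48 / 40 / 2) within the 0.2-cycle measurement
noise. `res$protein_props` completes the picture with per-protein
length, molecular weight (Da) and pI.

To analyse real data, point the same configuration keys at your own
FASTA/TSV files (genome + coordinate table, CDS and protein FASTAs,
primer table, Ct table); formats are documented in the function help
pages.

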