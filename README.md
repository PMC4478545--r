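# agamtools

Codon usage scoring, codon optimization, and sequence-level cloning
simulation for *Anopheles gambiae* transgenesis.

Transgenes from unrelated species — *Plasmodium* genes are the canonical
case — are often not expressed in the malaria mosquito because their
extremely AT-rich coding sequences rely on codons that highly expressed
*A. gambiae* genes rarely use. `agamtools` supports the complete design loop
for making such genes expressible and getting them into the genome:

* **Codon usage tables** (`count_codons()`, `build_frequency_table()`):
  per-codon counts, within-amino-acid frequencies, and per-1000 frequencies
  from any set of coding sequences; TSV import/export in a full and a compact
  "usage" dialect.
* **Translation penalty index** (`penalty_index()`): for a coding sequence of
  *n* codons with *k* codons whose within-amino-acid frequency in the
  reference table is strictly below a threshold *t* (default 10%),

      penalty index = 1000 · k / n

  — rare codons per 1000 codons, normalised against protein length. The
  per-rare-codon weight is a configuration hook.
* **Codon optimization** (`optimize_cds()`, `back_translate()`): synonymous
  recoding by `most_frequent`, `threshold_swap`, or seeded
  `weighted_sampling`, always preserving the protein, optionally excluding
  forbidden motifs on both strands (e.g. BsaI sites `GGTCTC`/`GAGACC` so
  inserts stay GoldenGate-compatible).
* **GoldenGate/BsaI assembly simulation** (`digest()`, `assemble()`): type
  IIS cut arithmetic (`GGTCTC(1/5)`, 4-nt 5' overhangs labelled by the
  top-strand 4-mer), stuffer release, and junction-graph assembly with named
  failure modes; exact-match in-silico PCR (`simulate_pcr()`).
* **Site-specific recombination** (`integrate_attB()`, `cre_recombine()`):
  phiC31 attB x attP integration producing attL/attR, and Cre/loxP cassette
  excision or inversion with full feature bookkeeping.
* **Deterministic synthetic fixtures** (`generate_goldengate_set()`,
  `generate_docking_locus()`, ...): every test input is generated from a
  seed; nothing needs to be downloaded.

A reference codon preference table in the style of a small set of nine
medium-to-highly expressed *A. gambiae* genes (10,160 codons) ships with the
package (`agam_reference_table()`). It is a clearly labelled **synthetic
stand-in** constructed to satisfy the documented marginal constraints — see
the methods vignette (`vignettes/agamtools-methods.Rmd`) — substitute a table
built from your own gene set for production design work.

## Worked example

```r
library(agamtools)

tab <- agam_reference_table()

# an AT-rich heterologous-style gene, 200 codons + stop
code <- standard_genetic_code()
set.seed(11)
at_rich <- names(code)[code != "*" & grepl("^[AT][AT]", names(code))]
csp_like <- coding_sequence(
  "csp_like",
  paste0(c(sample(at_rich, 200, replace = TRUE), "TAA"), collapse = "")
)

penalty_index(csp_like, tab)
#> <penalty_report> csp_like: 201 codons, 14 rare (< 0.1), penalty index 69.65 (~70 per 1000)

optimize_cds(csp_like, tab,
  optimization_spec("most_frequent", forbidden_motifs = c("GGTCTC", "GAGACC")))
#> <optimization_result> csp_like: penalty index 69.7 -> 0.0 (threshold 0.1)

# GoldenGate: destination + three donors -> unique circular product
gg <- generate_goldengate_set(n_donors = 3, seed = 1)
assemble(gg$destination, gg$donors)
#> <assembly_product> 716 bp circular; 4 fragments; junctions ATGA-CAGG-AAAC-CCCG

# docking-line derivation: integrate an attB plasmid, excise the lox cassette
locus <- generate_docking_locus(seed = 3)
integrant <- integrate_attB(locus, generate_attb_plasmid(seed = 4))
cre_recombine(integrant)[[1]][[1]]
#> <dna_molecule> docking_locus_3_integrant_excised: 1157 bp, linear, 4 feature(s)
#>   name start end strand
#>   attR   301 351      +
#>  cargo   352 751      +
#>   attL   752 803      +
#>   loxP   824 857      +
```

The scored sequence draws 14 of its 201 codons from below the 10% rarity
threshold, giving an index of ~70 rare codons per 1000; most-frequent
recoding removes all of them while keeping the protein identical and the
output free of BsaI sites. The assembly product is the designed
backbone-insert-insert-insert circle with its four junction overhangs, and
the excised docking locus retains the integrated cargo between attR/attL with
the single residual loxP that marks a clean Cre excision.

A command-line interface over the same functions is installed at
`inst/cli/agamtools.R` (subcommands `build-table`, `score`, `optimize`,
`digest`, `assemble`, `pcr`, `integrate`, `excise`, `make-fixtures`).

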