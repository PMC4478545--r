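---
title: "Scoring, recoding and assembling transgenes for Anopheles gambiae: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, recoding and assembling transgenes for Anopheles gambiae: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agamtools)
```

# The problem

Transgenes taken from unrelated species are often silent in the malaria
mosquito *Anopheles gambiae*: extremely AT-rich coding sequences (as in
*Plasmodium*) draw on codons that highly expressed mosquito genes rarely use,
and translation suffers. `agamtools` supports the full design loop that makes
such transgenes expressible: quantify codon usage in a reference gene set,
score a candidate coding sequence for rare-codon load, rewrite it
synonymously, and then simulate the standard cloning route into the mosquito
genome (GoldenGate/BsaI assembly of the transgenesis plasmid, phiC31
attB x attP docking-site integration, Cre/loxP marker excision, diagnostic
PCR).

# The translation penalty index

Given a reference codon usage table, every codon `c` encoding amino acid
`a(c)` has a within-amino-acid frequency

    f(c) = count(c) / sum over synonyms s of a(c) of count(s).

A codon is *rare* at threshold `t` when `f(c) < t` (strictly; a codon at
exactly the threshold is not penalised). With the default unit weight, a
coding sequence of `n` codons containing `k` rare codons scores

    penalty index = 1000 * k / n,

i.e. rare codons per 1000 codons, so that proteins of different lengths are
comparable. The default threshold is `t = 0.10`. Because the largest amino
acid family has six synonymous codons, the most frequent codon of any amino
acid has `f >= 1/6 > 0.10`: a sequence written entirely in most-frequent
codons always scores 0, and the index lives in `[0, 1000]`.

Three choices in the scorer were genuinely open and are resolved as follows:

* **Rarity is strict** (`f < t`, not `<=`): "used more rarely than the
  threshold" reads as a strict inequality, and ties are therefore not
  penalised.
* **The per-rare-codon weight is a hook.** The default weight is 1 per rare
  codon; `penalty_index(..., weight = )` accepts a constant or a function of
  `f` so that graded weightings (e.g. `1 - f`) can be calibrated if a
  different convention must be matched. The rare-codon calls themselves never
  depend on the weight.
* **Stop codons count.** A terminal stop is one codon of the message and is
  scored against stop-codon usage like any other codon; `exclude_stop = TRUE`
  removes it from both the numerator and denominator for comparison with
  amino-acid-only conventions. Reported integer indices use rounding half
  away from zero.

Codons of an amino acid never observed in the reference set have undefined
frequency; the scorer counts them as rare and warns. This is the conservative
choice: usage that was never observed cannot be endorsed.

# The packaged reference table

`agam_reference_table()` ships a 64-row codon preference table emulating a
small set of nine medium-to-highly expressed *A. gambiae* genes totalling
10,160 codons (10,151 sense codons plus one terminal stop per gene). The
table is **synthetic**: it is constructed from a fixed amino-acid composition
and fixed within-amino-acid codon weights (GC-ending codons preferred;
leucine TTA and arginine AGA/AGG rare), integerised by largest remainder so
the counts total exactly 10,160. Its filename
(`gambiae_reference_table_synthetic.tsv`) and header say so. It reproduces
the *structure* of an empirical preference table — per-amino-acid frequencies
summing to 1, per-1000 frequencies summing to 1000, realistic rare-codon
calls — and is suitable for demonstrations, tests, and calibration; for
production transgene design, build a table from your own gene set with
`count_codons()` + `build_frequency_table()` or load one with
`read_codon_table()`. The table deliberately reflects preference in a small
highly expressed gene set, not genome-wide usage.

# Codon optimization

`optimize_cds()` rewrites a coding sequence synonymously; the encoded protein
is asserted unchanged on every call. Three strategies:

* `most_frequent`: every codon becomes its amino acid's most frequent
  synonym (ties broken alphabetically, for determinism). Idempotent, and
  always reaches penalty 0.
* `threshold_swap`: only codons rarer than the threshold are replaced (by the
  most frequent synonym); everything else is left untouched, minimising
  sequence divergence from the input.
* `weighted_sampling`: synonyms are drawn in proportion to their reference
  frequency, **restricted to synonyms at or above the threshold**
  (renormalised), falling back to the most frequent synonym when none
  qualify. The restriction is deliberate: unrestricted frequency-weighted
  sampling would occasionally reintroduce rare codons and could raise the
  penalty; restricting the support guarantees the penalty never increases
  under any seed while still diversifying codon choice. Sampling is
  reproducible for a fixed `seed`.

The input's terminal stop codon is preserved verbatim: stop identity can
interact with 3' context and is not the optimizer's business.

**Motif avoidance.** `optimization_spec(forbidden_motifs = )` removes motifs
on both strands — the GoldenGate workflow passes `GGTCTC`/`GAGACC` so that
optimized inserts remain BsaI-free and assembly-compatible. Resolution is a
greedy left-to-right pass: for the left-most offending window, synonymous
alternatives are tried at each overlapped mutable codon in decreasing
frequency order until the window breaks; a window no substitution can break
raises `motif_conflict` with its position. Greedy resolution is a documented
heuristic: it does not search globally, and with dense motif sets it may
report a conflict a backtracking search could avoid.

# GoldenGate/BsaI assembly simulation

Molecules are double-stranded DNA represented by their top strand, linear or
circular, with optional named features. Coordinates are **1-based inclusive**
throughout, the GenBank/Bioconductor convention natural to R; command-line
and file output use the same convention, so there is no internal/external
coordinate shift to reason about.

BsaI is modelled as `GGTCTC(1/5)`: top strand cut 1 nt, bottom strand 5 nt
past the recognition motif, leaving 4-nt 5' overhangs. A cut is stored as the
position of the first base to the right of the top-strand cut plus the
overhang *label* — the top-strand 4-mer spanning the staggered cut, the same
convention used to annotate cohesive ends on assembly maps. Fragment
sequences are the top strand between consecutive top-strand cuts, so
digestion exactly conserves nucleotide content and religation is
concatenation. Ligation compatibility is label equality; palindromic labels
are allowed but flagged (self-ligation risk), and the fixture generator
refuses to design them.

`assemble()` digests the destination and every donor, identifies the
destination backbone (the released fragment free of recognition sites and of
the `lacZ`/stuffer feature) and exactly one recognition-free insert per donor,
and walks the junction graph from the backbone. Success requires the unique
closed cycle that uses the backbone once and every insert exactly once; a
dangling label raises `no_assembly` (naming the label), duplicated labels
raise `ambiguous_assembly`, and a donor releasing zero or several candidate
inserts raises `bad_donor`. The product is checked to contain no residual
recognition site and no stuffer. This is the *ideal-outcome* model: ligation
efficiency, partial digestion and thermocycling kinetics are wet-lab
variables deliberately out of scope.

In-silico PCR (`simulate_pcr()`) is exact-match only, with a 15-nt minimum
primer length: the forward primer on the top strand, the reverse primer's
reverse complement downstream, amplicon length measured 5' end to 5' end
inclusive. Circular templates amplify across the origin. All valid pairings
are enumerated; more than one is `ambiguous_pcr` (carrying every product),
none is `no_amplicon`. No mismatch or thermodynamic model is attempted —
the simulator answers "what does this primer pair amplify on this sequence",
not "will this PCR work".

# Recombination simulation

Site recognition is exact string matching on both strands; degenerate arms
are not modelled because no tolerance model is defined for them. attP and attB
are each (left arm, core, right arm) with an identical core (canonical TTG);
crossover at the core produces the hybrids attL = B-left + core + P-right and
attR = P-left + core + B-right. `integrate_attB()` requires exactly one attP
in the linear locus and one attB in the circular plasmid, inserts the full
plasmid, conserves total length, and leaves neither attP nor attB in the
integrant — without a recombination directionality factor the reaction is
one-way, so the absence of attP/attB (rather than reversibility) is the
testable claim, and attL x attR reversal is intentionally not modelled.

The default loxP is the canonical 34-nt site (13-8-13); the 8-nt spacer's
asymmetry defines orientation. Two sites in direct repeat excise the
intervening cassette (parent keeps one loxP; the cassette circularises with
the other), inverted sites flip the segment in place; both conserve
nucleotide content exactly. With more than two sites, all pairwise single
events are enumerated in position order — no kinetics, no iterated reaction.
The default att arm sequences are synthetic placeholders of realistic length:
real vectors use specific att variants, which should be supplied via
`recombination_sites()` or a YAML config. Features are remapped through every
operation; a feature crossing a cut or recombination joint is dropped rather
than guessed at.

# Synthetic fixtures and what the tests show

All test inputs are generated by seeded generators
(`generate_random_dna()`, `generate_cds_from_table()`,
`generate_goldengate_set()`, `generate_docking_locus()`,
`generate_attb_plasmid()`); a single documented RNG (R's Mersenne-Twister via
`set.seed`, never perturbing the caller's stream) makes every fixture
bit-reproducible, and `make-fixtures` records generator identity and seed in
its JSON manifest. The GoldenGate generator also returns the *designed*
assembled sequence, giving an oracle independent of the assembly walker: the
round-trip `assemble(generate_goldengate_set(...)) == designed` is checked
for donor counts 1, 3 and 5 over seeds 0-19.

Problem sizes used by the test suite and the acceptance script: 1,000 random
sequences of 10-300 codons for the penalty-oracle comparison; 100,000
sampled codons for table parameter recovery; 60 optimizer runs (3 strategies
x seeds 0-19) at 80 codons; 60 assemblies; 20 docking workflows. On the
recovery bound: with a 100,000-codon sample the rarest amino acids receive
only ~1,200-1,800 draws, so the 0.02 maximum-error bound sits near two
standard errors for their codon frequencies — it holds at the suite's fixed
seeds but is a statistical, not deterministic, guarantee.

Passing fixtures demonstrate internal consistency — cut arithmetic, label
chaining, crossover bookkeeping, conservation laws — on sequences with
uniform base composition and designed site placement. They do not demonstrate
performance on real plasmids, which have biased composition, repeated
elements, and occasionally near-cognate sites; nor do they validate the
synthetic reference table against measured *A. gambiae* expression. Scoring
of published gene sets requires supplying the corresponding sequences (see
`tests/testthat/test-acceptance.R` for the expected file layout under
`inst/extdata/external/`).

# Known limitations

* The packaged reference table is a constructed stand-in, not transcribed
  measurement data.
* Exact-match site and primer recognition only; no mismatch tolerance
  anywhere.
* Single-enzyme digests; no multi-enzyme one-pot simulation.
* Greedy motif avoidance may fail where backtracking would succeed.
* Cre enumeration is single-event; sequential recombination cascades must be
  simulated by re-invoking `cre_recombine()` on products.
* GenBank support covers simple and `complement()` spans with `/label`-style
  qualifiers — enough for plasmid maps, not for full-genome records
  (`join()` locations are not parsed).
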