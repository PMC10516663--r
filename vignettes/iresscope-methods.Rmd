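---
title: "Models and methods behind iresscope"
author: "iresscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind iresscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iresscope)
```

# The object being modeled

Dicistrovirus intergenic-region (IGR) IRESs are compact pseudoknotted RNAs
that recruit ribosomes without initiation factors and set translation of
the downstream capsid ORF going from a non-AUG codon. The package's default
grammar describes the most compact class ("type 6e", the Wenling class):

* **Domain 1 / PKII** — helices P1.1, P1.2 and P1.3 with the conserved
  L1.1a/L1.1b loops (which in the larger classes contact the 60S L1 stalk)
  and the variable L1.2a/L1.2b loops. P1.3 crosses P1.2, making PKII a
  genuine pseudoknot; P1.1 closes the domain around everything downstream
  through PKIII.
* **Domain 2 / PKIII** — an H-type pseudoknot of two helices, P2.1 and
  P2.2 (five base pairs each in the reference model), preceded by the
  single-stranded S1 element. Type 6e's PKIII carries no SLIV or SLV
  stem-loops; their presence instead marks types 6a/6b/6d.
* **Domain 3 / PKI** — the 3'-terminal pseudoknot (P3.1 crossed by P3.2)
  that mimics a codon:anticodon duplex; the initiation codon immediately
  follows P3.2's 3' strand.

Total length, including the first ORF2 codon, is constrained to 142–154 nt;
allowed initiation codons are GCU (Ala), ACU/ACC (Thr) and UCU/UCA/UCG
(Ser). An invariant G·U wobble pair is required at the junction of P1.1 and
L1.1a, reflecting the strict conservation of a P1/L1-junction wobble across
the class.

The concrete element order, bounds and motifs live in
`inst/extdata/descriptor_6e.yaml` and are user-editable. Two points where
the model required judgment:

* The loop consensus strings. The class's conserved loop motifs are
  summarized in the package as L1.1a = `GAUNU` (matched with zero
  mismatches), L1.1b = `GCU` (zero mismatches) and a weaker PKIII-loop
  consensus `ACA` on L2.2 (one mismatch allowed). The L1.1a/L1.1b strings
  are anchored on the positions that are both conserved across the class
  and functionally sensitive to substitution in the reference isolate; the
  L2.2 string is a package default standing in for the strong but less
  precisely charted conservation of the pseudoknot region, and should be
  re-derived from an alignment when one is available (`read_descriptor`
  accepts any replacement).
* Merged L1.2 loops. Some class members show a single enlarged L1.2
  instead of L1.2a/L1.2b; the descriptor represents this as the degenerate
  case `min_len(L1.2b) = 0`.

# The search

`match_descriptor` is a backtracking constraint search anchored at the 3'
end: IGR IRESs terminate in PKI abutting the initiation codon, so candidate
codons are enumerated from the 3' end of the window and the element chain
is placed right-to-left. A helix's length is fixed when its 3' strand is
placed; when its 5' strand is reached, antiparallel complementarity
(Watson-Crick, plus G·U where the helix allows wobble), required pairs and
the motif/mismatch budget are checked, and infeasible width intervals are
pruned against the total-length window. The search therefore enumerates
*all* satisfying placements; on 2-helix cut-down descriptors the test suite
verifies it against an exhaustive placement enumerator, and every emitted
match is re-validated by `validate_annotation`, an independent checker that
shares no code with the search.

Scores are `w_bp·(total base pairs) + w_motif·(matched consensus
positions) − w_energy·ΔG` with defaults `w_bp = 1`, `w_motif = 2`,
`w_energy = 0.1 (kcal/mol)⁻¹` — tuning knobs stored in the descriptor
config, not measured quantities. Ties break deterministically: lower ΔG,
then 5'-most, then shortest. IUPAC ambiguity codes in input never satisfy a
pair or motif position: uncertain sequence is not evidence.

The default search window is the last 260 nt of an IGR extract, enough for
the longest IGR IRES class plus flank when the extract ends shortly after
the true initiation codon. The scan pipeline (`run_scan`) faces a subtlety:
ORF2's reported start is provisional — it is a stop-to-stop frame boundary,
because IGR IRESs initiate at non-AUG codons — and can precede the true
codon by almost a full IRES length. `run_scan` therefore keeps
`flank + max(total_len_range)` nucleotides of ORF2 in the extract and
searches the whole of it, then fixes the ORF2 start from the best match
(`assign_ires_start`).

# Energetics

`evaluate_structure` implements the nearest-neighbor model at 37 °C with
the Turner/Mathews 1999 parameter tables packaged as plain text
(`inst/extdata/turner1999_params.txt`). That vintage was chosen because it
reproduces the package's reference hairpin value: the 24-nt T7-leader stem
(10 bp over a GUGA tetraloop) evaluates to −25.80 kcal/mol under the 1999
tables, whereas the 2004 revision gives −22.90 kcal/mol. The sum is
itemized (stacks, hairpin/bulge/internal terms, tetraloop bonuses, terminal
AU penalties, Ninio asymmetry, logarithmic extrapolation beyond 30 nt) so a
total can be audited against the tables by hand.

Simplifications, chosen deliberately because the evaluator's job is to
*rank* candidate placements of one element, not to fold arbitrary RNA:

* no coaxial stacking, no dangling ends, no exterior-loop terms;
* multibranch junctions carry zero penalty;
* pseudoknots are decomposed into non-crossing layers and summed with zero
  junction penalty. Loop terms are suppressed whenever the enclosed bases
  are paired in a crossing layer (an isolated pseudoknot stem is a
  junction, not a hairpin). Absolute ΔG values of pseudoknotted folds are
  therefore systematically more negative than a physical estimate; they
  are comparable *between placements*, which is all the score uses;
* generic internal-loop rules (initiation + mismatches + Ninio) rather
  than the special 1×1/1×2/2×2 tables.

Energy evaluation of plain hairpins is exact against the tables; the test
suite pins the reference hairpin and three additional hairpins
(wobble-closed triloop, bonus tetraloop) to values computed with an
independent implementation configured with the same parameter vintage.

# Comparative validation

A structural model earns credibility when its helices are maintained
across homologs either by strict conservation or by compensatory
substitutions. `covariation_report` classifies each proposed pair over an
alignment:

* **invariant** — every member carries one identical WC/G·U pair;
* **covariant** — complementarity is maintained in at least
  `ceil(strong_frac · n)` members *via at least two distinct pair
  identities* (the default `strong_frac = 0.85` generalizes a
  22-of-26-members rule so it scales with alignment size);
* **inconsistent** — otherwise.

Both the raw support count and the number of distinct pair identities are
reported, so stricter or looser readings of "covariant" can be recovered
from the output. Percent identity excludes columns gapped in either
sequence (identity definitions are program-specific; this one is fixed and
documented). The package aligns pairs of sequences (Gotoh affine-gap
global alignment, deterministic traceback, gap of length *k* costing
`open + k·extend` with defaults −5/−1) but does not build multiple
alignments — pre-aligned FASTA is accepted as-is, and the substitution-only
clade generator produces alignments that are trivially exact.

`probe_concordance` scores a model against chemical/enzymatic probing as
the fraction of reactive positions the model leaves unpaired; helix
positions, including helix-terminal and wobble-paired ones, count as
paired.

# Typing

`classify_type` applies architecture rules (which pseudoknots are present,
whether PKIII is a bare H-type or carries SLIV/SLV, whether SLIII decorates
PKI) plus the five length windows: 6c 126–132, 6e 142–154, 6d 161–168,
6a 176–193, 6b 195–205 nt. The windows are empirical, not definitional, so
an architecture that fits a type with a length in one of the inter-range
gaps yields `unclassified` with a near-type hint rather than a forced
call. `load_type_ranges` refuses overlapping custom ranges outright.
Start-codon compatibility is attached as evidence, never decisive. Two
points of judgment: published descriptions of types 6c and 6d are not
fully consistent with each other, and the package follows the schematic
reading — 6c has PKI and PKII but no PKIII, 6d has a PKIII with SLIV but no
SLV; and initiation-codon sets are only established for 6a/6b
({GCU, GCA, CAA}) and 6e, so 6c/6d provisionally reuse the 6a/6b set.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions the pipeline is validated under:

* clades of **26** members (the size of the reference class);
* per-site substitution rate **0.05** with compensation probability
  **0.9** — at rate 0.05 the simulated clades show roughly 60–95% pairwise
  identity and ~20–30% invariant columns, the regime reported for the real
  class;
* ORF1 of 250–350 codons carrying the YGDD RdRp-proxy motif, ORF2 of
  180–260 codons, IGR padding of 110–180 nt (placing the candidate IGR
  comfortably inside the scanner's 100–400 nt window);
* G·U wobble probability 0.1 per sampled helix pair.

Compensation restores *any* complementary pair, not necessarily the
ancestral identity — which is precisely what makes maintained pairs
covariant rather than invariant. Motif positions, required pairs and the
initiation codon are frozen during evolution by default (they are
class-defining); a flag unfreezes them for stress tests.

Two design decisions deserve explanation:

* **Helix-uniqueness guards.** A sampled IRES is useful as ground truth
  only if it is the *unique* best placement. After filling elements, the
  generator therefore repairs free loop bases so that no helix can be
  extended, slid strand-by-strand (±1–3 nt), or register-shifted (±1–2 nt)
  using chance-complementary neighbors, and the genome embedder applies
  the same guard at the IRES 5' boundary. In rare constrained geometries
  one marginal alternative register can survive; recovery checks therefore
  accept ±2 nt on the interval. Across seeds, best-match recovery is exact
  in ≥ 95% of cases.
* **Explicit RNG.** All sampling draws from an `rng_new()` instance
  (Mersenne-Twister state carried in the object, never the global stream),
  so every fixture is byte-identical under a fixed seed.

Decoys are Euler-path dinucleotide shuffles: exactly the same dinucleotide
(hence mononucleotide) composition as the source, randomized order. What
the generator does *not* emulate: indels (alignments are substitution-only
and exact), codon-usage or selection structure in the ORFs, covariation
shaped by a phylogeny rather than a star topology, and sequencing error.
Passing the recovery and covariation suites therefore demonstrates
correctness of the machinery under the stated model, not performance on
real metagenomic data — on real data, alignment quality and descriptor
breadth dominate.

# Numerical and interface choices

* Coordinates are 1-based inclusive everywhere, matching the notation in
  which a codon is written as positions 6906–6908; a zero-width loop is
  encoded as `end = start − 1`. (An earlier plan to use 0-based half-open
  coordinates internally was dropped: in R, 1-based indexing end to end
  removes a conversion layer and a class of off-by-one bugs.)
* Descriptor and range configs are YAML.
* Toeprint windows: the P-site state protects to +16–18 counting the
  codon's +1 nucleotide as position 1 (so +1 at 6906 gives 6921–6923);
  the alternate state to +19–21.
* Dot-bracket output is layered — one balanced bracket string per
  non-crossing layer, alphabets `()`, `[]`, `{}`, `<>` — with greedy
  assignment by ascending opening position, which attains the minimum
  (≤ 2 layers for every structure the 6e descriptor can emit; ≤ 3 is
  enforced for any descriptor).
* Full-size descriptors are validated to total lengths within 100–260 nt;
  the validator's floor is relaxed to 15 nt only so that cut-down 2-helix
  descriptors used in oracle tests are expressible.
* Test problem sizes: the exhaustive-oracle comparison runs 50 random
  60-mers against a toy descriptor; end-to-end recovery uses 20 seeded
  ~2 kb genomes; covariation suites use 26-member clades; decoy
  specificity uses 100 shuffles. These sizes give stable pass/fail
  behavior at desk scale.

# Known limitations

* The descriptor engine matches one element per sequence scan; nested or
  overlapping IRESs of different classes require separate descriptors and
  scans.
* Energetics are rank-quality only for pseudoknots (see above).
* `classify_type` consumes the package's own annotations; classifying a
  bare dot-bracket from elsewhere requires naming its elements first.
* The BLAST-based homology verification used in real screens is out of
  scope; the YGDD motif check is a lightweight proxy for "ORF1 encodes the
  polymerase", and capsid-order verification is not attempted.
* Reverse-strand scanning re-runs the forward scanner on the reverse
  complement; mixed-strand genomes (one cistron per strand) are not
  modeled.
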