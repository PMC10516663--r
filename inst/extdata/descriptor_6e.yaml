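# Structural descriptor for the compact Wenling-class (type 6e) IGR IRES.
#
# Architecture: domain 1 (pseudoknot PKII; helices P1.1-P1.3 with the L1.1
# and L1.2 loops), a type-specific H-type pseudoknot PKIII (helices P2.1 and
# P2.2) nested inside PKII, and the 3'-terminal pseudoknot PKI (helices P3.1
# and P3.2) whose 3' strand abuts the non-AUG initiation codon of ORF2.
# Total length, including the first ORF2 codon, is 142-154 nt.
#
# Loop consensus strings: the L1.1a and L1.1b consensus positions are the
# ones shown to be conserved across the class and functionally sensitive to
# substitution (L1.1a GA-U-N-U; L1.1b GCU); the short PKIII loop consensus is
# a package default standing for the strong class-specific conservation of
# the pseudoknot region.
name: "6e"
total_len_range: [142, 154]
allowed_start_codons: [GCU, ACU, ACC, UCU, UCA, UCG]
pk3_is_h_type: true
score_weights: {bp: 1.0, motif: 2.0, energy: 0.1}
wobble_prob: 0.1
score_min: 0.0
helices:
  P1.1: {min_bp: 3, max_bp: 6, allow_wobble: true,
         required_pairs: [{offset: -1, kind: GU}]}   # invariant wobble at the P1/L1 junction
  P1.2: {min_bp: 5, max_bp: 11, allow_wobble: true}  # most length-variable helix
  P1.3: {min_bp: 4, max_bp: 6, allow_wobble: true}
  P2.1: {min_bp: 4, max_bp: 7, allow_wobble: true}   # five pairs in the reference model
  P2.2: {min_bp: 4, max_bp: 7, allow_wobble: true}
  P3.1: {min_bp: 4, max_bp: 7, allow_wobble: true}
  P3.2: {min_bp: 4, max_bp: 7, allow_wobble: true}
loops:
  L1.1a: {min_len: 6, max_len: 10, motif: GAUNU, max_mismatch: 0}
  L1.2a: {min_len: 2, max_len: 6}
  L1.2b: {min_len: 0, max_len: 4}    # degenerate (0 nt) for merged-L1.2 variants
  L1.1b: {min_len: 5, max_len: 8, motif: GCU, max_mismatch: 0}
  S1:    {min_len: 10, max_len: 18}
  L2.1a: {min_len: 2, max_len: 5}
  L2.2:  {min_len: 3, max_len: 6, motif: ACA, max_mismatch: 1}
  L2.1b: {min_len: 4, max_len: 8}
  L3.1a: {min_len: 2, max_len: 5}
  L3.2:  {min_len: 4, max_len: 8}
# 5'->3' order of helix strands and loops. P1.3 crosses P1.2 (making PKII a
# pseudoknot), P2.2 crosses P2.1 (the H-type PKIII, enclosed by P1.1), and
# P3.2 crosses P3.1 (PKI). The initiation codon follows P1.1/P3.2 directly.
order: [P1.1_5p, L1.1a, P1.2_5p, L1.2a, P1.3_5p, L1.2b, P1.2_3p, L1.1b,
        P1.3_3p, S1, P2.1_5p, L2.1a, P2.2_5p, L2.2, P2.1_3p, L2.1b, P2.2_3p,
        P1.1_3p, P3.1_5p, L3.1a, P3.2_5p, L3.2, P3.1_3p, P3.2_3p]
pk_groups:
  PKI:   [P3.1, P3.2]
  PKII:  [P1.1, P1.2, P1.3]
  PKIII: [P2.1, P2.2]
domains:
  "1": [P1.1, P1.2, P1.3, L1.1a, L1.1b, L1.2a, L1.2b]
  "2": [S1, P2.1, P2.2, L2.1a, L2.1b, L2.2]
  "3": [P3.1, P3.2, L3.1a, L3.2]
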