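# RNA nearest-neighbor free-energy parameters at 37 C, kcal/mol
# Turner/Mathews 1999 parameter set (Mathews, Sabina, Zuker & Turner,
# J Mol Biol 288:911-940, 1999), the vintage used by classic mfold 3.x.
# Pair row/column order in STACK and mismatch blocks: CG GC GU UG AU UA
# STACK entry [p1][p2]: helix pair p1=(i,j) stacked on p2=(j-1,i+1).
# Loop initiation tables are indexed by loop size 1..30; INF = forbidden.
SECTION STACK
  -2.40  -3.30  -2.10  -1.40  -2.10  -2.10
  -3.30  -3.40  -2.50  -1.50  -2.20  -2.40
  -2.10  -2.50   1.30  -0.50  -1.40  -1.30
  -1.40  -1.50  -0.50   0.30  -0.60  -1.00
  -2.10  -2.20  -1.40  -0.60  -1.10  -0.90
  -2.10  -2.40  -1.30  -1.00  -0.90  -1.30
SECTION HAIRPIN
   1      INF
   2      INF
   3     5.70
   4     5.60
   5     5.60
   6     5.40
   7     5.90
   8     5.60
   9     6.40
  10     6.50
  11     6.60
  12     6.70
  13     6.78
  14     6.86
  15     6.94
  16     7.01
  17     7.07
  18     7.13
  19     7.19
  20     7.25
  21     7.30
  22     7.35
  23     7.40
  24     7.44
  25     7.49
  26     7.53
  27     7.57
  28     7.61
  29     7.65
  30     7.69
SECTION BULGE
   1     3.80
   2     2.80
   3     3.20
   4     3.60
   5     4.00
   6     4.40
   7     4.59
   8     4.70
   9     4.80
  10     4.90
  11     5.00
  12     5.10
  13     5.19
  14     5.27
  15     5.34
  16     5.41
  17     5.48
  18     5.54
  19     5.60
  20     5.65
  21     5.71
  22     5.76
  23     5.80
  24     5.85
  25     5.89
  26     5.94
  27     5.98
  28     6.02
  29     6.05
  30     6.09
SECTION INTERNAL
   1      INF
   2     4.10
   3     5.10
   4     1.70
   5     1.80
   6     2.00
   7     2.20
   8     2.30
   9     2.40
  10     2.50
  11     2.60
  12     2.70
  13     2.78
  14     2.86
  15     2.94
  16     3.01
  17     3.07
  18     3.13
  19     3.19
  20     3.25
  21     3.30
  22     3.35
  23     3.40
  24     3.45
  25     3.49
  26     3.53
  27     3.57
  28     3.61
  29     3.65
  30     3.69
SECTION MISMATCH_HAIRPIN
PAIR CG
  -1.50  -1.50  -1.40  -1.80
  -1.00  -0.90  -2.90  -0.80
  -2.20  -2.00  -1.60  -1.10
  -1.70  -1.40  -1.80  -2.00
PAIR GC
  -1.10  -1.50  -1.30  -2.10
  -1.10  -0.70  -2.40  -0.50
  -2.40  -2.90  -1.40  -1.20
  -1.90  -1.00  -2.20  -1.50
PAIR GU
   0.20  -0.50  -0.30  -0.30
  -0.10  -0.20  -1.50  -0.20
  -0.90  -1.10  -0.30   0.00
  -0.30  -0.30  -0.40  -1.10
PAIR UG
  -0.50  -0.30  -0.60  -0.50
  -0.20  -0.10  -1.70   0.00
  -0.80  -1.20  -0.30  -0.70
  -0.60  -0.10  -0.60  -0.80
PAIR AU
  -0.30  -0.50  -0.30  -0.30
  -0.10  -0.20  -1.50  -0.20
  -1.10  -1.20  -0.20   0.20
  -0.30  -0.30  -0.60  -1.10
PAIR UA
  -0.50  -0.30  -0.60  -0.50
  -0.20  -0.10  -1.20   0.00
  -1.40  -1.20  -0.70  -0.20
  -0.30  -0.10  -0.50  -0.80
SECTION MISMATCH_INTERNAL
PAIR CG
   0.00   0.00  -1.10   0.00
   0.00   0.00   0.00   0.00
  -1.10   0.00   0.00   0.00
   0.00   0.00   0.00  -0.70
PAIR GC
   0.00   0.00  -1.10   0.00
   0.00   0.00   0.00   0.00
  -1.10   0.00   0.00   0.00
   0.00   0.00   0.00  -0.70
PAIR GU
   0.70   0.70  -0.40   0.70
   0.70   0.70   0.70   0.70
  -0.40   0.70   0.70   0.70
   0.70   0.70   0.70   0.00
PAIR UG
   0.70   0.70  -0.40   0.70
   0.70   0.70   0.70   0.70
  -0.40   0.70   0.70   0.70
   0.70   0.70   0.70   0.00
PAIR AU
   0.70   0.70  -0.40   0.70
   0.70   0.70   0.70   0.70
  -0.40   0.70   0.70   0.70
   0.70   0.70   0.70   0.00
PAIR UA
   0.70   0.70  -0.40   0.70
   0.70   0.70   0.70   0.70
  -0.40   0.70   0.70   0.70
   0.70   0.70   0.70   0.00
SECTION TETRALOOP
GGGGAC   0.20
GGUGAC   0.20
CGAAAG   0.40
GGAGAC   0.20
CGCAAG   0.40
GGAAAC   0.20
CGGAAG   0.40
CUUCGG   0.80
CGUGAG   0.40
CGAAGG   1.50
CUACGG   1.30
GGCAAC   0.70
CGCGAG   0.90
UGAGAG   2.30
CGAGAG   1.40
AGAAAU   2.50
CGUAAG   1.40
CUAACG   2.20
UGAAAG   2.80
GGAAGC   2.70
GGGAAC   1.70
UGAAAA   2.70
AGCAAU   3.00
AGUAAU   3.00
CGGGAG   1.90
AGUGAU   3.00
GGCGAC   1.70
GGGAGC   2.70
GUGAAC   2.20
UGGAAA   2.70
SECTION MISC
TERMINAL_AU 0.50
NINIO_M 0.50
NINIO_MAX 3.00
LXC 1.078560
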