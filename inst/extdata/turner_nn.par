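# locopt nearest-neighbor free energy parameters (kcal/mol, 37 C)
# Turner-style tables: Watson-Crick stacking after Xia et al. 1998,
# wobble stacks at published magnitudes, size-dependent loop
# initiation with Jacobson-Stockmayer extrapolation beyond the
# measured sizes. No dangles, no coaxial stacking.
# stack
# rows and columns ordered AU CG GC UA GU UG; entry (r,c) is the
# stack of inner pair c directly under outer pair r
  -0.93  -2.24  -2.08  -1.10  -0.55  -1.36
  -2.11  -3.26  -2.36  -2.08  -1.41  -2.11
  -2.35  -3.42  -3.26  -2.24  -1.53  -2.51
  -1.33  -2.35  -2.11  -0.93  -1.27  -1.00
  -1.00  -2.51  -2.11  -1.36  -0.50   0.47
  -1.27  -1.53  -1.41  -0.55  -0.57  -0.50
# hairpin
# loop sizes 1..30
 INF INF   5.40   5.60   5.70   5.40   6.00   5.50   6.40   6.50
   6.60   6.70   6.78   6.86   6.94   7.01   7.07   7.13   7.19   7.25
   7.30   7.35   7.40   7.44   7.49   7.53   7.57   7.61   7.65   7.68
# bulge
   3.80   2.80   3.20   3.60   4.00   4.40   4.57   4.71   4.84   4.95
   5.05   5.15   5.23   5.31   5.39   5.46   5.52   5.58   5.64   5.70
   5.75   5.80   5.85   5.90   5.94   5.98   6.02   6.06   6.10   6.14
# interior
 INF   1.50   1.60   1.70   1.80   2.00   2.17   2.31   2.44   2.55
   2.65   2.75   2.83   2.91   2.99   3.06   3.12   3.18   3.24   3.30
   3.35   3.40   3.45   3.50   3.54   3.58   3.62   3.66   3.70   3.74
# ML_params
# multiloop closing / per-unpaired / per-branch
  3.40   0.00   0.40
# NINIO
# interior-loop asymmetry: per-nucleotide slope and cap
  0.50   3.00
# Terminal_AU
  0.50
# END
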