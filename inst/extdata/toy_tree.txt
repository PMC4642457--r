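# Condensed rCRS-anchored haplogroup skeleton. The tree is rooted at an
# L3-like ancestor; edges on the rCRS side carry '@' cancellations so that
# the cumulative motif of H2a2a (the rCRS anchor) is empty. Motifs along the
# C1b path follow the published mitogenome variant table; the C1b sub-clade
# motifs (C1b2/C1b6/C1b13) are illustrative placeholders, not Phylotree's.
L3 73 263 750 1438 2706 4769 7028 8701 8860 9540 10398 10873 11719 12705 14766 15301 15326 16223
  N @8701 @9540 @10398 @10873 @15301
    W5a1a1a 57 60+T
    R @12705 @16223
      R0 @73 @11719
        HV @14766
          H @2706 @7028
            H2 @1438
              H2a @4769
                H2a2 @750
                  H2a2a @263 @8860 @15326
  M 489 10400 14783 15043
    M8 4715 7196A 8584 15487T 16298
      CZ 249d
        C 3552A 9545 11914 13263 14318 16327
          C1 290-291d 16325
            C1b 493
              C1b2 194
              C1b6 16311
              C1b13 16092
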