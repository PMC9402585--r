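# 21-gene recurrence-score algorithm: gene groups, coefficients, clamps and
# risk-category thresholds (Paik et al., N Engl J Med 2004). Expression is
# log2, reference-normalized against the mean of the five reference genes
# and shifted by `offset` onto the 0-15 expression convention.
reference_genes: [ACTB, GAPDH, GUSB, RPLP0, TFRC]
offset: 10
groups:
  grb7:
    weights: {GRB7: 0.9, ERBB2: 0.1}
    floor: 8
  er:
    weights: {ESR1: 0.2, PGR: 0.3, BCL2: 0.25, SCUBE2: 0.25}
  proliferation:
    weights: {MKI67: 0.2, AURKA: 0.2, BIRC5: 0.2, CCNB1: 0.2, MYBL2: 0.2}
    floor: 6.5
  invasion:
    weights: {CTSL2: 0.5, MMP11: 0.5}
  cd68:
    weights: {CD68: 1.0}
  gstm1:
    weights: {GSTM1: 1.0}
  bag1:
    weights: {BAG1: 1.0}
coefficients:
  grb7: 0.47
  er: -0.34
  proliferation: 1.04
  invasion: 0.10
  cd68: 0.05
  gstm1: -0.08
  bag1: -0.07
rescale: {scale: 20, shift: 6.7, min: 0, max: 100}
categories: {low_below: 18, high_from: 31}
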