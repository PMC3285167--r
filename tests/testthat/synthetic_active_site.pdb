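REMARK synthetic five-atom active-site mockup for selection tests
ATOM      1  OE2 GLU A  22       0.000   0.000   0.000  1.00  0.00           O
ATOM      2  HE2 GLU A  22       1.000   0.000   0.000  1.00  0.00           H
ATOM      3  O   HOH A  99       3.000   0.000   0.000  1.00  0.00           O
ATOM      4  H1  HOH A  99       3.800   0.300   0.000  1.00  0.00           H
ATOM      5  O2' ABA A   7       6.000   0.000   0.000  1.00  0.00           O
END
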