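[
  {
    "q1": 3, "n1": 5, "k1": 4, "d_H": 2,
    "comment": "single parity check code over GF(3); MDS at these parameters",
    "G": [[1,0,0,0,1],[0,1,0,0,1],[0,0,1,0,2],[0,0,0,1,2]]
  },
  {
    "q1": 3, "n1": 6, "k1": 4, "d_H": 2,
    "comment": "double parity extension over GF(3); d=3 is unattainable at [6,4] over GF(3) (an information set would need 4 pairwise non-proportional all-nonzero rows in GF(3)^2, but only 2 projective classes exist)",
    "G": [[1,0,0,0,1,1],[0,1,0,0,1,2],[0,0,1,0,2,1],[0,0,0,1,2,2]]
  },
  {
    "q1": 3, "n1": 6, "k1": 5, "d_H": 2,
    "comment": "single parity check code over GF(3); MDS at these parameters",
    "G": [[1,0,0,0,0,1],[0,1,0,0,0,1],[0,0,1,0,0,1],[0,0,0,1,0,2],[0,0,0,0,1,2]]
  },
  {
    "q1": 4, "n1": 6, "k1": 3, "d_H": 4,
    "comment": "hexacode-equivalent [6,3,4] over GF(4); MDS-like optimum beyond RS length",
    "G": [[1,0,0,3,2,3],[0,1,0,2,2,1],[0,0,1,3,1,1]]
  },
  {
    "q1": 4, "n1": 6, "k1": 4, "d_H": 2,
    "comment": "double parity extension over GF(4); d=3 is unattainable at [6,4] over GF(4) (only 3 projective classes of all-nonzero rows in GF(4)^2)",
    "G": [[1,0,0,0,1,1],[0,1,0,0,1,2],[0,0,1,0,2,1],[0,0,0,1,3,1]]
  }
]
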