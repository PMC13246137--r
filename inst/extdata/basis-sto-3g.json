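{
  "H": [
    {"l": 0,
     "exponents": [3.42525091, 0.62391373, 0.16885540],
     "coeffs": [0.15432897, 0.53532814, 0.44463454]}
  ],
  "C": [
    {"l": 0,
     "exponents": [71.6168370, 13.0450960, 3.5305122],
     "coeffs": [0.15432897, 0.53532814, 0.44463454]},
    {"l": 0,
     "exponents": [2.9412494, 0.6834831, 0.2222899],
     "coeffs": [-0.09996723, 0.39951283, 0.70011547]},
    {"l": 1,
     "exponents": [2.9412494, 0.6834831, 0.2222899],
     "coeffs": [0.15591627, 0.60768372, 0.39195739]}
  ],
  "N": [
    {"l": 0,
     "exponents": [99.1061690, 18.0523120, 4.8856602],
     "coeffs": [0.15432897, 0.53532814, 0.44463454]},
    {"l": 0,
     "exponents": [3.7804559, 0.8784966, 0.2857144],
     "coeffs": [-0.09996723, 0.39951283, 0.70011547]},
    {"l": 1,
     "exponents": [3.7804559, 0.8784966, 0.2857144],
     "coeffs": [0.15591627, 0.60768372, 0.39195739]}
  ],
  "O": [
    {"l": 0,
     "exponents": [130.7093200, 23.8088610, 6.4436083],
     "coeffs": [0.15432897, 0.53532814, 0.44463454]},
    {"l": 0,
     "exponents": [5.0331513, 1.1695961, 0.3803890],
     "coeffs": [-0.09996723, 0.39951283, 0.70011547]},
    {"l": 1,
     "exponents": [5.0331513, 1.1695961, 0.3803890],
     "coeffs": [0.15591627, 0.60768372, 0.39195739]}
  ]
}
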