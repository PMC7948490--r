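{
  "isoform_label": "Myo1C35-dTH1",
  "temperature_C": 20,
  "units": {
    "bimolecular": "uM^-1 s^-1",
    "unimolecular": "s^-1"
  },
  "rates": {
    "k1_plus": 4.1,
    "k1_minus": 1650,
    "k2_plus": 37,
    "k2_minus": 6.9,
    "k3diss_plus": 10.1,
    "k3diss_minus": 0.01,
    "khyd": 75,
    "k9_plus": 1.2,
    "k9_minus": 26.6,
    "k4_plus": 0.1,
    "k4_minus": 0.08,
    "k5_plus": 0.86,
    "k5_minus": 3.94,
    "kA_plus": 2.27,
    "kA_minus": 0.037,
    "kalpha_plus": 3.9,
    "kalpha_minus": 1.05
  },
  "kintek_aliases": {
    "k+1": 4.1,
    "k-1": 1650,
    "k+2": 37,
    "k-2": 6.9,
    "k+3": 10.1,
    "k-3": 0.01,
    "k+4": 75,
    "k+5": 1.2,
    "k-5": 26.6,
    "k+6": 0.1,
    "k-6": 0.08,
    "k+7": 0.86,
    "k-7": 3.94,
    "k+8": 2.27,
    "k-8": 0.037,
    "k+9": 3.9,
    "k-9": 1.05
  },
  "derived": {
    "K_alpha": 3.71428571428571,
    "K_A_nM": 16.2995594713656,
    "K_9": 22.1666666666667,
    "K_2": 5.36231884057971,
    "inv_K_1": 402.439024390244,
    "K_5": 0.218274111675127
  }
}
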