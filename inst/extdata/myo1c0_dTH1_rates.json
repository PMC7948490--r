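{
  "isoform_label": "Myo1C0-dTH1",
  "temperature_C": 20,
  "units": {
    "bimolecular": "uM^-1 s^-1",
    "unimolecular": "s^-1"
  },
  "rates": {
    "k1_plus": 4,
    "k1_minus": 621,
    "k2_plus": 37,
    "k2_minus": 1,
    "k3diss_plus": 10.1,
    "k3diss_minus": 0.01,
    "khyd": 75,
    "k9_plus": 0.79,
    "k9_minus": 8.53,
    "k4_plus": 0.1,
    "k4_minus": 0.08,
    "k5_plus": 1.66,
    "k5_minus": 3.94,
    "kA_plus": 1.47,
    "kA_minus": 0.019,
    "kalpha_plus": 4.2,
    "kalpha_minus": 4.72
  },
  "kintek_aliases": {
    "k+1": 4,
    "k-1": 621,
    "k+2": 37,
    "k-2": 1,
    "k+3": 10.1,
    "k-3": 0.01,
    "k+4": 75,
    "k+5": 0.79,
    "k-5": 8.53,
    "k+6": 0.1,
    "k-6": 0.08,
    "k+7": 1.66,
    "k-7": 3.94,
    "k+8": 1.47,
    "k-8": 0.019,
    "k+9": 4.2,
    "k-9": 4.72
  },
  "derived": {
    "K_alpha": 0.889830508474576,
    "K_A_nM": 12.9251700680272,
    "K_9": 10.7974683544304,
    "K_2": 37,
    "inv_K_1": 155.25,
    "K_5": 0.421319796954315
  }
}
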