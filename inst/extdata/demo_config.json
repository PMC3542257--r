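{
  "simulate": {
    "n_coding": 400,
    "n_ncrna": 40,
    "genome_length": 400000,
    "resolution": 22,
    "n_replicates": 2,
    "category_scheme": {
      "cell wall synthesis": 0.08,
      "iron acquisition": 0.05,
      "DNA replication": 0.04,
      "translation": 0.3,
      "PBSX prophage": 0.009,
      "transcription factors": 0.2,
      "other metabolism": 0.321
    },
    "effects": {
      "frac_direct_up": 0.225,
      "frac_indirect_down": 0.075,
      "noise_sd_probe_affinity": 0.15,
      "noise_sd_replicate": 0.1
    }
  },
  "lvs_fraction": 0.4,
  "lfdr_max": 0.1,
  "amplitude_min": 1.6,
  "grid": { "from": 1.0, "to": 4.0, "by": 0.05 },
  "bandwidth": 0.5,
  "bh_q": 0.05,
  "slope_min": 1e-4,
  "seed": 1
}
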