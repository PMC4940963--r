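{
  "doses": [
    {
      "antigen": "BCG",
      "series": "BCG",
      "dose_index": 1,
      "recommended_age_days": 0,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": true
    },
    {
      "antigen": "OPV0",
      "series": "OPV",
      "dose_index": 0,
      "recommended_age_days": 0,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": false
    },
    {
      "antigen": "OPV1",
      "series": "OPV",
      "dose_index": 1,
      "recommended_age_days": 42,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": true,
      "companion": "PENTA1"
    },
    {
      "antigen": "OPV2",
      "series": "OPV",
      "dose_index": 2,
      "recommended_age_days": 70,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": true,
      "companion": "PENTA2"
    },
    {
      "antigen": "OPV3",
      "series": "OPV",
      "dose_index": 3,
      "recommended_age_days": 98,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": true,
      "companion": "PENTA3"
    },
    {
      "antigen": "PENTA1",
      "series": "PENTA",
      "dose_index": 1,
      "recommended_age_days": 42,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": true,
      "companion": "OPV1"
    },
    {
      "antigen": "PENTA2",
      "series": "PENTA",
      "dose_index": 2,
      "recommended_age_days": 70,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": true,
      "companion": "OPV2"
    },
    {
      "antigen": "PENTA3",
      "series": "PENTA",
      "dose_index": 3,
      "recommended_age_days": 98,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": true,
      "companion": "OPV3"
    },
    {
      "antigen": "PCV1",
      "series": "PCV",
      "dose_index": 1,
      "recommended_age_days": 42,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": false
    },
    {
      "antigen": "PCV2",
      "series": "PCV",
      "dose_index": 2,
      "recommended_age_days": 70,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": false
    },
    {
      "antigen": "PCV3",
      "series": "PCV",
      "dose_index": 3,
      "recommended_age_days": 98,
      "early_margin_days": 4,
      "delay_margin_days": 14,
      "in_fic": false
    },
    {
      "antigen": "MV",
      "series": "MV",
      "dose_index": 1,
      "recommended_age_days": 274,
      "early_margin_days": 4,
      "delay_margin_days": 30,
      "in_fic": true
    }
  ],
  "fic_cutoff_days": 365,
  "rollout_dates": {
    "PCV": "2011-02-01"
  }
}
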