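{
  "type": "hospital_config",
  "name": "small_hospital",
  "n_trauma_units_max": 4,
  "trauma_unit_mobilization": {
    "office": [
      [0, 1],
      [15, 2],
      [30, 4]
    ],
    "non-office": [
      [0, 1],
      [20, 2],
      [45, 4]
    ]
  },
  "n_minor_units": 4,
  "n_or_theatres": 2,
  "or_clearance_min": 30,
  "or_initial_occupied": 1,
  "n_icu_beds": 3,
  "icu_reserve_ventilators": 1,
  "icu_reserve_delay_min": 60,
  "n_ward_beds": 40,
  "ct_in_ed": true,
  "ct_transport_min": 10,
  "n_ct": 1,
  "transport_staff_mobilization": {
    "office": [
      [0, 2],
      [30, 4]
    ],
    "non-office": [
      [0, 1],
      [30, 4]
    ]
  },
  "transfer_min": 5,
  "transfer_fallback_category": "nurse",
  "staff_roster": {
    "office": {
      "physician": [
        [0, 6],
        [20, 12],
        [40, 18]
      ],
      "nurse": [
        [0, 12],
        [30, 24],
        [60, 40]
      ],
      "surgeon": [
        [0, 6],
        [30, 12]
      ],
      "icu_nurse": [
        [0, 6],
        [60, 9]
      ]
    },
    "non-office": {
      "physician": [
        [0, 3],
        [30, 12],
        [60, 18]
      ],
      "nurse": [
        [0, 6],
        [30, 20],
        [60, 40]
      ],
      "surgeon": [
        [0, 2],
        [30, 8],
        [60, 12]
      ],
      "icu_nurse": [
        [0, 4],
        [60, 9]
      ]
    }
  },
  "supplies": {
    "chest_drain_set": 10,
    "surgical_disposables": 30,
    "ext_fixation_set": 6,
    "blood_units": 80
  },
  "restock": null,
  "alert_offset_min": 5,
  "or_icu_blocking": true,
  "horizon_min": 600
}
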