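{
  "subpops": {
    "HC": {
      "name": "HC",
      "K_max": 123,
      "dynamic": false,
      "K_decay_range": [0.1, 0.6],
      "K_floor": 0,
      "flood_probability": 0,
      "mortality": {
        "juvenile": {
          "baseline": 0.38,
          "flood": 0.38,
          "post_flood": 0.38,
          "increment": 0,
          "window": 0,
          "cap": 0.38
        },
        "adult": {
          "baseline": 0.19,
          "flood": 0.19,
          "post_flood": 0.19,
          "increment": 0,
          "window": 0,
          "cap": 0.19
        }
      },
      "fecundity": {
        "baseline": 1.06,
        "flood": 1.06,
        "post_flood": 1.06
      },
      "ev_sd_fraction": 0.2,
      "initial_males": 62,
      "initial_females": 61
    },
    "M1F": {
      "name": "M1F",
      "K_max": 3448,
      "dynamic": true,
      "K_decay_range": [0.1, 0.6],
      "K_floor": 0,
      "flood_probability": 0.05,
      "mortality": {
        "juvenile": {
          "baseline": 0.55,
          "flood": 0.95,
          "post_flood": 0.3,
          "increment": 0.04,
          "window": 3,
          "cap": 0.9
        },
        "adult": {
          "baseline": 0.24,
          "flood": 0.35,
          "post_flood": 0.2,
          "increment": 0.015,
          "window": 1,
          "cap": 0.27
        }
      },
      "fecundity": {
        "baseline": 0.84,
        "flood": 0,
        "post_flood": 1.8
      },
      "ev_sd_fraction": 0.2,
      "initial_males": 100,
      "initial_females": 100
    },
    "M2": {
      "name": "M2",
      "K_max": 70,
      "dynamic": false,
      "K_decay_range": [0.1, 0.6],
      "K_floor": 0,
      "flood_probability": 0,
      "mortality": {
        "juvenile": {
          "baseline": 0.62,
          "flood": 0.62,
          "post_flood": 0.62,
          "increment": 0,
          "window": 0,
          "cap": 0.62
        },
        "adult": {
          "baseline": 0.25,
          "flood": 0.25,
          "post_flood": 0.25,
          "increment": 0,
          "window": 0,
          "cap": 0.25
        }
      },
      "fecundity": {
        "baseline": 1.56,
        "flood": 1.56,
        "post_flood": 1.56
      },
      "ev_sd_fraction": 0.2,
      "initial_males": 35,
      "initial_females": 34
    }
  },
  "dispersal": {
    "baseline": {
      "adult": [
        [0, 0.0284869976359338, 0.0215130023640662],
        [0.00707547169811321, 0, 0.0429245283018868],
        [0.00553505535055351, 0.0444649446494465, 0]
      ],
      "juvenile": [
        [0, 0.0626713947990544, 0.0473286052009456],
        [0.0155660377358491, 0, 0.0944339622641509],
        [0.0121771217712177, 0.0978228782287823, 0]
      ]
    },
    "flood": {
      "adult": [
        [0, 0.00291668518222451, 0.0215130023640662],
        [0.0383453823476265, 0, 0.232628652908934],
        [0.00553505535055351, 0.00455261192649803, 0]
      ],
      "juvenile": [
        [0, 0.00641670740089392, 0.0473286052009456],
        [0.0843598411647782, 0, 0.511783036399654],
        [0.0121771217712177, 0.0100157462382957, 0]
      ]
    },
    "post_flood": {
      "adult": [
        [0, 0.0782139296240044, 0.0215130023640662],
        [0.00707547169811321, 0, 0.0429245283018868],
        [0.00553505535055351, 0.122082997162191, 0]
      ],
      "juvenile": [
        [0, 0.17207064517281, 0.0473286052009456],
        [0.0155660377358491, 0, 0.0944339622641509],
        [0.0121771217712177, 0.268582593756821, 0]
      ]
    }
  },
  "replicates": 1000,
  "horizon": 100,
  "max_age": 20,
  "sex_ratio": 0.5,
  "seed": 1
}
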