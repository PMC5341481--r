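{
  "window_length": 147,
  "K": {
    "AA": 13.2431,
    "AC": 10.1735,
    "AG": 33.824,
    "AT": 5.3292,
    "CA": 7.9983,
    "CC": 7.067,
    "CG": 6.6974,
    "CT": 11.6149,
    "GA": 7.4093,
    "GC": 41.4949,
    "GG": 26.3069,
    "GT": 9.2165,
    "TA": 34.6707,
    "TC": 8.201,
    "TG": 8.2287,
    "TT": 7.3692
  },
  "theta0": {
    "AA": -0.2417,
    "AC": -0.2424,
    "AG": -0.056,
    "AT": 0.2707,
    "CA": -0.2601,
    "CC": -0.0713,
    "CG": -0.2979,
    "CT": -0.0362,
    "GA": 0.1696,
    "GC": 0.0466,
    "GG": 0.1253,
    "GT": 0.1424,
    "TA": -0.0635,
    "TC": 0.1531,
    "TG": -0.1781,
    "TT": 0.1334
  },
  "kappa": 20,
  "amplitude": 0.2,
  "period": 10,
  "phase": 0,
  "lambda": 0,
  "beta": 6
}
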