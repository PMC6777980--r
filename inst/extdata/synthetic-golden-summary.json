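{
  "associations": [
    {
      "method": "spearman",
      "mode": "symmetric",
      "coefficient": 0.937148735490118,
      "p": 2.1259084781785e-13,
      "ciLow": 0.814336699960186,
      "ciHigh": 0.975917905124032,
      "nEdges": 28,
      "seed": 101
    },
    {
      "method": "pearson_log",
      "mode": "symmetric",
      "coefficient": 0.956646827731929,
      "p": 1.90122372504497e-15,
      "ciLow": 0.930293403698422,
      "ciHigh": 0.973744979488042,
      "nEdges": 28,
      "seed": 101
    },
    {
      "method": "partial_spearman",
      "mode": "symmetric",
      "coefficient": 0.939792008757526,
      "p": 3.68221572126958e-13,
      "nEdges": 28,
      "seed": 101
    },
    {
      "method": "spearman",
      "mode": "directed",
      "coefficient": 0.877479234445513,
      "p": 7.1845345550334e-19,
      "ciLow": 0.765529839308442,
      "ciHigh": 0.93294526974636,
      "nEdges": 56,
      "seed": 101
    },
    {
      "method": "pearson_log",
      "mode": "directed",
      "coefficient": 0.934861956509603,
      "p": 5.95607848849757e-26,
      "ciLow": 0.899763341819586,
      "ciHigh": 0.957552268276293,
      "nEdges": 56,
      "seed": 101
    },
    {
      "method": "partial_spearman",
      "mode": "directed",
      "coefficient": 0.878398300512773,
      "p": 1.25322288824737e-18,
      "nEdges": 56,
      "seed": 101
    }
  ],
  "detection": [
    {
      "density": 0.1,
      "densityRealized": 0.107142857142857,
      "mode": "matched",
      "sensitivity": 1,
      "specificity": 1,
      "precision": 1
    },
    {
      "density": 0.1,
      "densityRealized": 0.107142857142857,
      "mode": "sweep",
      "sensitivity": 0.964285714285714,
      "specificity": 0.535714285714286,
      "precision": 0.331482611317825
    },
    {
      "density": 0.2,
      "densityRealized": 0.214285714285714,
      "mode": "matched",
      "sensitivity": 0.5,
      "specificity": 0.863636363636364,
      "precision": 0.5
    },
    {
      "density": 0.2,
      "densityRealized": 0.214285714285714,
      "mode": "sweep",
      "sensitivity": 0.839285714285714,
      "specificity": 0.569805194805195,
      "precision": 0.463078601320458
    },
    {
      "density": 0.3,
      "densityRealized": 0.321428571428571,
      "mode": "matched",
      "sensitivity": 0.777777777777778,
      "specificity": 0.894736842105263,
      "precision": 0.777777777777778
    },
    {
      "density": 0.3,
      "densityRealized": 0.321428571428571,
      "mode": "sweep",
      "sensitivity": 0.817460317460317,
      "specificity": 0.62406015037594,
      "precision": 0.624734115132614
    },
    {
      "density": 0.4,
      "densityRealized": 0.428571428571429,
      "mode": "matched",
      "sensitivity": 0.916666666666667,
      "specificity": 0.9375,
      "precision": 0.916666666666667
    },
    {
      "density": 0.4,
      "densityRealized": 0.428571428571429,
      "mode": "sweep",
      "sensitivity": 0.800595238095238,
      "specificity": 0.694196428571429,
      "precision": 0.778721106990534
    },
    {
      "density": 0.5,
      "densityRealized": 0.5,
      "mode": "matched",
      "sensitivity": 0.928571428571429,
      "specificity": 0.928571428571429,
      "precision": 0.928571428571429
    },
    {
      "density": 0.5,
      "densityRealized": 0.5,
      "mode": "sweep",
      "sensitivity": 0.760204081632653,
      "specificity": 0.724489795918367,
      "precision": 0.830640240555762
    },
    {
      "density": 0.6,
      "densityRealized": 0.607142857142857,
      "mode": "matched",
      "sensitivity": 0.882352941176471,
      "specificity": 0.818181818181818,
      "precision": 0.882352941176471
    },
    {
      "density": 0.6,
      "densityRealized": 0.607142857142857,
      "mode": "sweep",
      "sensitivity": 0.701680672268908,
      "specificity": 0.766233766233766,
      "precision": 0.890165910588915
    },
    {
      "density": 0.7,
      "densityRealized": 0.714285714285714,
      "mode": "matched",
      "sensitivity": 1,
      "specificity": 1,
      "precision": 1
    },
    {
      "density": 0.7,
      "densityRealized": 0.714285714285714,
      "mode": "sweep",
      "sensitivity": 0.660714285714286,
      "specificity": 0.839285714285714,
      "precision": 0.949593844159062
    },
    {
      "density": 0.8,
      "densityRealized": 0.821428571428571,
      "mode": "matched",
      "sensitivity": 0.956521739130435,
      "specificity": 0.8,
      "precision": 0.956521739130435
    },
    {
      "density": 0.8,
      "densityRealized": 0.821428571428571,
      "mode": "sweep",
      "sensitivity": 0.599378881987578,
      "specificity": 0.857142857142857,
      "precision": 0.972699487078369
    },
    {
      "density": 0.9,
      "densityRealized": 0.928571428571429,
      "mode": "matched",
      "sensitivity": 0.923076923076923,
      "specificity": 0,
      "precision": 0.923076923076923
    },
    {
      "density": 0.9,
      "densityRealized": 0.928571428571429,
      "mode": "sweep",
      "sensitivity": 0.543956043956044,
      "specificity": 0.821428571428571,
      "precision": 0.986158191072787
    }
  ],
  "meta": {
    "seed": 101,
    "B": 500,
    "level": 0.95,
    "modes": ["symmetric", "directed"],
    "nRegions": 8,
    "inputHashes": {
      "regions": "37546d916d2973c5683cf70a23805827",
      "tracing": "905dd9109e61d6348b422a3ea15d01d8",
      "tractography": "e802db339eb3baae7fab9aae3d291f00"
    },
    "package": "0.1.0"
  }
}
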