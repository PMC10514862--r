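{
  "accepted_maps": {
    "PD": {
      "units": "arbitrary"
    },
    "T1": {
      "units": "ms"
    },
    "T2": {
      "units": "ms"
    }
  },
  "presets": {
    "3T": {
      "models": {
        "DIR": {
          "equation": "abs(PD*(1-2*exp(-TI2/T1)+2*exp(-(TI1+TI2)/T1)-exp(-TR/T1))*exp(-TE/T2))",
          "maps": [
            "PD",
            "T1",
            "T2"
          ],
          "parameters": {
            "TE": {
              "default": 80,
              "max": 800,
              "min": 0
            },
            "TI1": {
              "default": 2208,
              "max": 22080,
              "min": 0
            },
            "TI2": {
              "default": 545,
              "max": 5450,
              "min": 0
            },
            "TR": {
              "default": 6670,
              "max": 66700,
              "min": 0
            }
          },
          "title": "Double inversion recovery"
        },
        "FLAIR": {
          "equation": "abs(PD*exp(-TE/T2)*exp(-TSAT/T1)*(1-2*exp(-TI/T1)))",
          "maps": [
            "PD",
            "T1",
            "T2"
          ],
          "parameters": {
            "TE": {
              "default": 80,
              "max": 800,
              "min": 0
            },
            "TI": {
              "default": 2075,
              "max": 20750,
              "min": 0
            },
            "TSAT": {
              "default": 1405,
              "max": 14050,
              "min": 0
            }
          },
          "title": "T2-FLAIR with T1 saturation"
        },
        "GRE": {
          "equation": "PD*(1-exp(-TR/T1))",
          "maps": [
            "PD",
            "T1"
          ],
          "parameters": {
            "TR": {
              "default": 113,
              "max": 1130,
              "min": 0
            }
          },
          "title": "T1w gradient-recalled echo"
        },
        "GenericIR": {
          "equation": "abs(PD*(1-2*exp(-TI/T1))*(1-exp(-TR/T1))*exp(-TE/T2))",
          "maps": [
            "PD",
            "T1",
            "T2"
          ],
          "parameters": {
            "TE": {
              "default": 1,
              "max": 10,
              "min": 0
            },
            "TI": {
              "default": 795,
              "max": 7950,
              "min": 0
            },
            "TR": {
              "default": 5020,
              "max": 50200,
              "min": 0
            }
          },
          "title": "Generic inversion-recovery signal model"
        },
        "MP2RAGE": {
          "equation": "abs(1-2*exp(-TI/T1))",
          "maps": [
            "T1"
          ],
          "parameters": {
            "TI": {
              "default": 1816,
              "max": 18160,
              "min": 0
            }
          },
          "title": "Bias-free T1w uniform (MP2RAGE-like)"
        },
        "SE": {
          "equation": "PD*(1-exp(-TR/T1))*exp(-TE/T2)",
          "maps": [
            "PD",
            "T1",
            "T2"
          ],
          "parameters": {
            "TE": {
              "default": 80,
              "max": 800,
              "min": 0
            },
            "TR": {
              "default": 8000,
              "max": 80000,
              "min": 0
            }
          },
          "title": "T2w spin echo"
        },
        "TBE": {
          "equation": "abs(PD*(1-2*exp(-TI/T1))*(1-exp(-TR/T1))*exp(-TE/T2))",
          "maps": [
            "PD",
            "T1",
            "T2"
          ],
          "parameters": {
            "TE": {
              "default": 1,
              "max": 10,
              "min": 0
            },
            "TI": {
              "default": 795,
              "max": 7950,
              "min": 0
            },
            "TR": {
              "default": 5020,
              "max": 50200,
              "min": 0
            }
          },
          "title": "Tissue border enhancement"
        }
      }
    }
  }
}
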