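{
  "seed": 42,
  "n_cells": 60,
  "n_cancer": 10,
  "total_cycles": 20,
  "domain": "u",
  "domain_params": {"width": 8, "height": 8, "base_height": 5,
                    "lumen_halfwidth": 1},
  "glucose": {"D": 10, "target_mean": 0.5, "basal_frac": 0.02},
  "homeo": {"A_up": 1.1, "eta": 0.03},
  "gate": true
}
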