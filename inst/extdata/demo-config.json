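{
  "seed": 42,
  "stages": ["synth", "simulate", "score", "metrics", "lda", "cellcycle"],
  "simulate": {"composition": "1:3", "n_cells": 8},
  "synth": {"n_leaders": 15, "n_followers": 45, "n_cells_cycle": 25}
}
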