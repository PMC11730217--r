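{
  "required": ["provenance", "thermodynamics", "cells"],
  "provenance_required": ["package_version", "config_hash", "replica_seeds",
                          "timestamp"],
  "cell_required": ["variant", "condition", "status"],
  "cell_required_ok": ["variant", "condition", "status", "n_frames",
                       "distributions", "reactive_fraction",
                       "stacking_counts", "carboxylate_proximity",
                       "replicas"]
}
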