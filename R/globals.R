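# Column names used inside dplyr/ggplot2 non-standard evaluation.
utils::globalVariables(c("treatment", "replicate", "count", "compartment",
                         "P", "condition"))
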