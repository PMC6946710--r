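# column names used inside ggplot2::aes()
utils::globalVariables(c("fraction_switched", "r", "used", "label", "mean",
                         "sem", "y"))
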