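# Shared constants, defined first in file load order because other files use
# them in load-time initializers.

BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")
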