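Placeholder directory for optional external data.

The streak-statistics acceptance test looks here for the behavioral
source-data container figure1e_sourcedata.mat (a MAT v5 file of per-fish
signed turn angles). It is not redistributed with the package; place it
in this directory before installing to enable that check.
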