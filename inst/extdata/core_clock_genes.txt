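# Core clock genes excluded from "non-core-clock" variability-index runs.
# One symbol per line; edit freely. Nr1d1/Nr1d2 = Rev-erb alpha/beta,
# Rorc = Ror gamma, Ciart = Gm129.
Per1
Per2
Cry2
Dbp
Nr1d1
Nr1d2
Tef
Hlf
Ciart
Rorc
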