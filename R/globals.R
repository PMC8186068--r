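# let data.table find := and [.data.table despite namespace-qualified calls
.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  "cpg_id", "gene", "features", "feature", "w", "gi", "fracSig",
  "chromIdx", "ordkey", "gidx", "pos", "shared", "g"))
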