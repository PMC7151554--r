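# shared constructors for hand-built EPC sets

make_epcs <- function(origins, prok_members, euk_members) {
  n <- length(origins)
  epcs <- data.frame(epc_id = sprintf("EPC_%d", seq_len(n)),
                     euk_family = sprintf("F%d", seq_len(n)),
                     origin = origins,
                     bact_families = "", arch_families = "",
                     stringsAsFactors = FALSE)
  pres <- do.call(rbind, lapply(seq_len(n), function(i) rbind(
    data.frame(epc_id = epcs$epc_id[i], genome_id = prok_members[[i]],
               domain = ifelse(grepl("^a", prok_members[[i]], ignore.case = TRUE),
                               "archaea", "bacteria"),
               stringsAsFactors = FALSE),
    data.frame(epc_id = epcs$epc_id[i], genome_id = euk_members[[i]],
               domain = "eukaryote", stringsAsFactors = FALSE))))
  epcAncestry:::new_epc_set(epcs, presence = pres)
}
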