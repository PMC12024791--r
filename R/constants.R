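# State layout: 16 species as (inactive, active) pairs for the seven
# conserved proteins, then the two DUSP tiers.  The active form carries a
# "p" suffix (phosphorylated); dusp is the transcript, DUSP the protein.
STATE_NAMES <- c("R", "Rp", "Ras", "Rasp", "Raf", "Rafp", "MEK", "MEKp",
                 "ERK", "ERKp", "NFB", "NFBp", "PFB", "PFBp",
                 "dusp", "DUSP")

PAIR_SPECIES <- c("R", "Ras", "Raf", "MEK", "ERK", "NFB", "PFB")
# index of (inactive, active) columns for each pair
PAIR_IDX <- cbind(inactive = seq(1, 13, by = 2), active = seq(2, 14, by = 2))
ERKP_IDX <- 10L
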