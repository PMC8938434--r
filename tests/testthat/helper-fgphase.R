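# shared fixtures for the suite

sp600 <- spin_parameters(600)

repeat_unit <- "GGLFGGNTQPAT"

proton_shifts <- function() {
  st <- synthetic_shift_table()
  st[st$atom != "N", ]
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
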