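# Shared fixture builders; everything is generated in code at test time.

# two-point Fe(II) profile whose 15-18 m slope is exactly 7.07e-4 umol cm-4
feII_two_point_profile <- function() {
  depth_profile("FeII", c(15, 18), c(0, 212.1), "uM")
}

write_profile_csv <- function(path, rows) {
  writeLines(c("depth_m,analyte,value,unit", rows), path)
}

# a randomly scaled balanced reaction built from the packaged registry
random_registry_reaction <- function(eqs) {
  eqs[[sample(length(eqs), 1)]]
}
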