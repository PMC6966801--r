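# shared fixtures: a canonical one-sided design and interim look

ref_design <- function() {
  design_spec(alpha = 0.025, sidedness = "one", power = 0.9, effect = 0.3)
}

ref_interim <- function(z = 1, t = 0.5, estimate = NULL, se = NULL) {
  interim_state(z = z, info_fraction = t, estimate = estimate, se = se)
}

# registry written to a temp file for I/O round trips
write_temp_registry <- function(registry) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write_registry(registry, path)
  path
}
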