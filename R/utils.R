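# Deterministic child seed derivation (Lehmer-style step), so one master
# seed reproducibly drives several independent RNG streams and adding a
# stream never perturbs the others. Kept within the 32-bit integer range.
child_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i) * 16807
  as.integer(s %% 2147483646) + 1L
}

#' Package version string
#' @return Character scalar.
#' @keywords internal
alecontrast_version <- function() {
  as.character(utils::packageVersion("alecontrast"))
}
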