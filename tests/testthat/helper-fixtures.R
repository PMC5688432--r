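# Shared fixtures built in code.

# Proximate inputs echoing a high-fertility, low-use country (Mali-like):
# proportion married 85%, PPI 11.7 months, 2.2% childless at 45-49,
# all-method CPR 11%, effectiveness 95%, TAR from 31 abortions/1000 women.
mali_inputs <- function(tfr_for_ca = 6.1) {
  proximate_inputs(
    proportion_married = 0.85, ppi_months = 11.7, pct_childless_45_49 = 2.2,
    cpr = 0.11, effectiveness = 0.95, tar = tar_from_abortion_rate(31),
    tfr_for_ca = tfr_for_ca
  )
}

# Inputs under which every fertility index is exactly 1.
identity_inputs <- function(tfr_for_ca = 15) {
  proximate_inputs(
    proportion_married = 1, ppi_months = 1.5, pct_childless_45_49 = 3,
    cpr = 0, effectiveness = 0.95, tar = 0, tfr_for_ca = tfr_for_ca
  )
}

# Independent oracle for the composed TFR: literal transcription of the
# index formulas, kept separate from the package's vectorised path.
oracle_tfr <- function(pm, ppi, s, cpr, e, tar, tfr_prev, tf) {
  cm <- pm
  ci <- 20 / (18.5 + ppi)
  cs <- (7.63 - 0.11 * s) / 7.3
  ca <- tfr_prev / (tfr_prev + 0.4 * (1 + cpr) * tar)
  cc <- 1 - 1.08 * cpr * e
  cm * ci * ca * cs * cc * tf
}
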