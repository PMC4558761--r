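# Shared fixtures: default constants and the twelve-class patient grid,
# built once per test run.
cn_default <- patient_constants()
t1 <- patient_classes(cn_default)

# printed V/Q columns of the twelve simulated patient classes (2 dp)
vq_printed <- data.frame(
  high = c(1.15, 3.64, 3.85, 4.09, 6.82, 7.27, 10.18, 7.79, 10.91, 8.39,
           11.75, 14.27),
  low  = c(1.15, 0.94, 1.00, 1.06, 0.76, 0.81, 0.48, 0.87, 0.52, 0.93,
           0.56, 0.28))

# noise-free single measurement simulated from a parameter pair
clean_measurement <- function(fs, fa, fio2, cn = cn_default) {
  sim <- gx_simulate(fs, fa, fio2, cn)
  gx_measurement(fio2, sim$pao2, sim$paco2, cn)
}
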