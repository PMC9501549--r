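# Shared fixtures: the baseline parameter set is loaded once; protocols are
# cheap to rebuild per test.
p0 <- default_parameters()

# quick integration settings used where solver accuracy is not the point
fast <- list(dt_out = 0.01, rtol = 1e-6, atol = 1e-10)

integrate_fast <- function(p, proto, ...) {
  integrate_network(p, proto, dt_out = fast$dt_out, rtol = fast$rtol,
                    atol = fast$atol, ...)
}
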