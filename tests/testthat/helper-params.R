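# Worked-example parameter set used across the suite: mu = 2 comorbidities
# per year, 80% signal quality, 10% discounting, half-year expected wait,
# 10-year post-transplant vs 2-year no-transplant life expectancy.
ex_params <- function() {
  fontan_params(mu = 2, theta = 0.8, r = 0.1, delta = 0.5, LT = 10, LNT = 2)
}

ex_thresholds <- function() listing_thresholds(ex_params())
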