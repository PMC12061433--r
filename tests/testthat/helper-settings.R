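# The statistical acceptance blocks can accumulate several expectation
# failures in one run; keep the reporter from aborting the session so the
# remaining files always execute.
options(testthat.progress.max_fails = 1000L)
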