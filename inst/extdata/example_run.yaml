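# Evaluate the packaged potato trial tables, each year separately plus the
# two-year average, with the package's default hierarchy and data-driven
# quantile grade schemes.
tables:
  builtin: potato
pooled: true
combination:
  negative_alpha_policy: fallback_equal
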