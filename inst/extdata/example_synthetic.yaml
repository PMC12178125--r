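# Synthetic factorial trial mirroring the biochar study design:
# 300/500/700 degC x 10/20/30 t/ha plus an untreated control, two years.
# Omitted surface columns fall back to the package defaults (all apexes
# at 500 degC, 20 t/ha; noise sd 2% of each indicator's surface range).
temperature_levels: [300, 500, 700]
rate_levels: [10, 20, 30]
include_control: true
years: 2
derive_economics: true
tuber_price: 1600        # CNY per tonne of fresh tubers
fixed_costs: 17115       # CNY/ha: water 580 + fertilizer 4535 + other 12000
biochar_price: 0         # CNY per tonne of biochar, charged in year 1
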