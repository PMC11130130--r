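# Self-sufficiency scenario inputs for Sub-Saharan Africa, 2020 -> 2050.
# Current production/demand/yield are external statistics (FAOSTAT-style
# 2018-2020 averages) taken as inputs; the 2050 scenario yields follow the
# trend projection (same_rate) and the yield-gap closure achieved by
# high-technology farmers (acceleration). Area held fixed.
area_mha: 40
current_yield: 2
current_production: 80
current_demand: 79
demand_2050: 184
gain_rate: 0.027
horizon_years: 30
yield_potential: 10.6
scenario_yields_2050:
  same_rate: 2.7
  acceleration: 4.2
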