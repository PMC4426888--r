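# Balanced, targeted and sustainable support (BTS).
# Patch over the neutral base tables. Encodes: a small-farm subsidy (lower
# cessation for farms < 10 DSU), a flat-rate payment cap (reduced expansion
# resources of large market-oriented farms), compulsory green public goods
# (less cutting, more planting of landscape elements in protection zones),
# diversification subsidies in LEADER zones, and a tourism feedback on
# landscape quality.
name: BTS
cessation:
  small_farm_subsidy: 0.60
  leader_diversified_mult: 0.75
expansion:
  participation_mult: 0.85
  propensity_mult: 0.70
  productivity_floor: 0.05
  zone_mult:
    agri_development: 1.10
    habitat_directive: 0.60
    landscape_protection: 0.80
market:
  p_nature:
    habitat_directive: 0.10
    landscape_protection: 0.05
elements:
  base:
    expansionist:               {cut: 0.030, keep: 0.9325, plant: 0.0375}
    conventional:               {cut: 0.020, keep: 0.9405, plant: 0.0395}
    diversified_multifunctional: {cut: 0.010, keep: 0.9405, plant: 0.0495}
    hobby:                      {cut: 0.010, keep: 0.948, plant: 0.042}
    resident:                   {cut: 0.010, keep: 0.9345, plant: 0.0555}
  protect_cut_mult: 0.30
  protect_plant_mult: 1.60
tourism:
  gain: 0.50
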