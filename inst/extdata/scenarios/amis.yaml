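# Abolition of market and income support (AMIS).
# Patch over the neutral base tables. Encodes: no small-farm support (price-
# cost squeeze pushes low-productivity farms out), intensified expansion on
# productive land, nature organisations buying ecologically significant
# parcels, widespread hedgerow/tree-line removal outside protected zones,
# and no tourism feedback.
name: AMIS
cessation:
  small_farm_subsidy: 1.00
  low_productivity_mult: 4.00
expansion:
  participation_mult: 1.10
  propensity_mult: 1.20
  productivity_floor: 0.17
  zone_mult:
    agri_development: 1.50
    habitat_directive: 0.50
    landscape_protection: 0.70
market:
  p_nature:
    habitat_directive: 0.50
    landscape_protection: 0.30
elements:
  base:
    expansionist:               {cut: 0.055, keep: 0.930, plant: 0.015}
    conventional:               {cut: 0.040, keep: 0.945, plant: 0.015}
    diversified_multifunctional: {cut: 0.025, keep: 0.955, plant: 0.020}
    hobby:                      {cut: 0.020, keep: 0.960, plant: 0.020}
    resident:                   {cut: 0.015, keep: 0.955, plant: 0.030}
  protect_cut_mult: 0.50
  protect_plant_mult: 1.00
tourism:
  gain: 0.0
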