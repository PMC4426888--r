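# Default synthetic-region configuration: the 2005 baseline of the case
# region. Counts are reproduced exactly, areas to within rounding.
n_farmers: 1705
agri_area_ha: 45765
semi_natural_ha: 5045
pct_residents: 38
resident_parcels: 2
type_mix:
  expansionist: 0.35
  conventional: 0.34
  diversified_multifunctional: 0.31
  hobby: 0.0
cell_m: 100
age_mean: 55
age_sd: 10
age_min: 25
age_max: 75
retire_age_mean: 65
retire_age_sd: 5
contiguous_frac: 0.6
scatter_radius_m: 16500
zone_fracs:
  landscape_protection: 0.15
  habitat_directive: 0.10
  agri_development: 0.25
  leader: 0.20
  pilot: 0.08
attraction_frac: 0.0002
element_total_km: 5000
element_gamma_shape: 1.2
element_protect_mult: 2
n_villages: 12
start_year: 2005
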