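# Emerald ash borer (Agrilus planipennis) model parameters.
# Temperatures in degC; durations and limits in degree-days (degC).

# lower developmental thresholds
egg_ldt = 12.2
larvae_ldt = 12.2
pupae_ldt = 12.2
adult_ldt = 12.2

# upper developmental thresholds
egg_udt = 36.0
larvae_udt = 36.0
pupae_udt = 36.0
adult_udt = 36.0

# stage durations
egg_dd = 172
larvae_dd = 700        # instar 1 to J-larval formation
pup_dd = 135
adult_dd = 145

# phenological event offsets (ow_event_dd varies; derived from the cohorts)
egg_event_dd = 172     # egg hatch
larvae_event_dd = 700  # J-larval formation
pupae_event_dd = 135   # adult emergence (pupal development complete)
adult_event_dd = 72    # egg laying

# cold stress
coldstress_threshold = -31
coldstress_units_max1 = 80
coldstress_units_max2 = 160

# heat stress
heatstress_threshold = 38
heatstress_units_max1 = 75
heatstress_units_max2 = 150

# overwintering-cohort completion distribution
distro_mean = 200
distro_var = 15000
xdist1 = 60
xdist2 = 350
distro_shape = lognormal
n_cohorts = 7

# other
stgorder = OL,P,A,E,L
obligate_diapause = 1
calctype = triangle
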