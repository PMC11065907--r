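# Default calibration of the synthetic hatch-experiment generator.
# These are package calibration values chosen to produce realistic magnitudes
# for P. ulmi winter eggs (hatch success rising from under ~10% after 10 d of
# chilling to ~60-70% after 100 d, strongest response near 4 C, higher under
# long photoperiod; median hatch times falling from ~50 d to ~12 d), not
# estimates from any particular dataset.
hatch_logit_intercept: -2.8     # logit hatch probability at 0 chill days, short photoperiod, optimal chill temp
chill_day_coef: 0.033           # logit increase per chill day
chill_day_cap: 100              # days beyond which extra chilling adds nothing
photoperiod_long_bonus: 0.8     # logit bonus under long (16:8 L:D) photoperiod
chill_temp_optimum: 4           # C, chill temperature maximising hatch
chill_temp_curvature: 0.02      # logit penalty per (C deviation from optimum)^2
t50_base: 52                    # days, median hatch time extrapolated to 0 chill days
t50_decay: 0.4                  # days of median hatch time lost per chill day
t50_floor: 12                   # days, minimum median hatch time
hatch_time_cv: 0.6              # coefficient of variation of individual hatch times;
                                # wide enough that slow arenas show some early
                                # emergence instead of being closed unhatched by
                                # the two-flat-checks censoring protocol
observation_interval: 10        # days between hatch counts
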