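# Editable stage-dependent physiology defaults for the synthetic cohort
# simulator (synthetic conventions, not measured clinical values).
# Stage order everywhere: WAKE, N1N2, N3, REM.
hr_by_stage: [65, 60, 55, 62]          # beats/min
hrv_sd_by_stage: [60, 40, 25, 70]      # ms beat-to-beat SD
rsa_amp_by_stage: [0.010, 0.025, 0.035, 0.015]   # s, RSA modulation of RR
resp_rate_by_stage: [14, 15, 13, 16]   # breaths/min
resp_irregularity_by_stage: [0.10, 0.05, 0.02, 0.20]
resp_axis: [0.2, 0.1, 0.97]            # unit-normalized on load
resp_amp_g: 0.010
posture_change_rate: 1.5               # events/hour
wake_motion_burst_rate: 20             # events/hour of wake
accel_noise_g: 0.002
ecg_noise: 0.03
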