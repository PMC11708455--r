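# Calibration cohort: two-arm repeat-ablation study world.
# Population analytic means per arm x phase; between-patient SDs solved once
# from the reported paired-test significance at n = 43 / 29 (see the
# methods vignette for the derivation). PTFV1 magnitudes are mV.ms
# (depth x negative-phase duration); PWD/PWDisp ms; PWV = 12-lead sum, mV.
n_success: 43
n_fail: 29
fs: 1000
duration_s: 60
seed: 1
noise.white_sd_uv: 15
noise.wander_amp_uv: 100
noise.wander_hz: 0.25
noise.mains_amp_uv: 30
noise.mains_hz: 50

success.pre.pwd_mean: 136.7
success.pre.pwd_sd: 23
success.pre.pwdisp_mean: 29.7
success.pre.pwv_mean: 1.2
success.pre.pwv_sd: 0.35
success.pre.ptf_mean: 3.1
success.pre.ptf_sd: 2.0
success.pre.ptf_width_ms: 45
success.pre.width_jitter_sd: 1.5
success.pre.hr_mean: 72
success.pre.hr_sd: 5

success.post.pwd_mean: 123.5
success.post.pwd_sd: 23
success.post.pwdisp_mean: 28.2
success.post.pwv_mean: 1.3
success.post.pwv_sd: 0.35
success.post.ptf_mean: 4.4
success.post.ptf_sd: 2.0
success.post.ptf_width_ms: 45
success.post.width_jitter_sd: 1.5
success.post.hr_mean: 72
success.post.hr_sd: 5

fail.pre.pwd_mean: 135.4
fail.pre.pwd_sd: 13.4
fail.pre.pwdisp_mean: 30.2
fail.pre.pwv_mean: 1.3
fail.pre.pwv_sd: 0.35
fail.pre.ptf_mean: 2.9
fail.pre.ptf_sd: 0.94
fail.pre.ptf_width_ms: 45
fail.pre.width_jitter_sd: 1.5
fail.pre.hr_mean: 72
fail.pre.hr_sd: 5

fail.post.pwd_mean: 125.3
fail.post.pwd_sd: 13.4
fail.post.pwdisp_mean: 28.6
fail.post.pwv_mean: 1.3
fail.post.pwv_sd: 0.35
fail.post.ptf_mean: 2.7
fail.post.ptf_sd: 0.94
fail.post.ptf_width_ms: 45
fail.post.width_jitter_sd: 1.5
fail.post.hr_mean: 72
fail.post.hr_sd: 5
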