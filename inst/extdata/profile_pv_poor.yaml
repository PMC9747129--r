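# Steady-state serum TXB2 profile of the poor-responder PV calibration
# under chronic 100 mg once-daily aspirin.
task: profile
scenario: pv_poor
dose_mg: 100
regimen: qd
out_prefix: pv_poor_qd
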