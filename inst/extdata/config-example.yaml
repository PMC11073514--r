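# Example configuration for the cardiox-simulate command-line tool.
protocol: sev2       # control | sev1 | sev2 | ir
drug: levo           # none | levo
dose_um: 2           # 0.3 | 2 | 10 (interpolation allowed)
duration: 1050       # seconds; omit for the protocol standard
rtol: 1.0e-6
atol: 1.0e-8
dt_fine: 0.001
out: cardiox-out
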