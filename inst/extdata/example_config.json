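{"E_B": 0.6, "E_U": 0.25, "k_A_app": 300, "k_D": 100,
 "rate_ms": 100, "duration": 0.3, "n_traj": 3, "condition": "demo"}
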