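# Glass-electrode LFP under anesthesia: 10 s Welch windows, 0.1 Hz step,
# 50% overlap; normalization over 0.1-100 Hz.
mode: anesthetized_lfp
seed: 1
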