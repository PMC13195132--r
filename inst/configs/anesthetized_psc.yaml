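# Voltage-clamp synaptic currents: 2 s Welch windows, 0.5 Hz step, 90%
# overlap; normalization over 0.1-300 Hz; paired LFP for phase locking.
mode: anesthetized_psc
seed: 1
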