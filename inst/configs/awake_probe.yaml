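# Awake silicon-probe recording: pyramidal-layer channel selection, run/rest
# and T/D state segmentation, SWR detection, unit classification, bursts,
# putative PV+ basket cells.
mode: awake_probe
seed: 1
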