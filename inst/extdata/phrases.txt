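fall off
fall from
fell off
fell from
run over
hit by
struck by
kilometre per hour
jumped off
knocked over
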