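sample_id	group
green_01	green
green_02	green
green_03	green
red_01	red
red_02	red
red_03	red
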