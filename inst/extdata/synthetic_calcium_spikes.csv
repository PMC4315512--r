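time,amplitude
6.5546863432973623,
7.6988470274955034,
12.042013495229185,
16.150327981449664,
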