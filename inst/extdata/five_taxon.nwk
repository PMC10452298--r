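(x:560,(v:540,(u:343,(y:101,z:101):242):197):20);
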