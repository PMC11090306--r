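50d9ee2c007376d2514cb15491bbd362
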