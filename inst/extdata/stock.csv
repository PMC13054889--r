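id,source
BB-AMINE-1,internal
BB-BORONIC-1,commercial
BB-ARYLCL-1,internal
CCO,commercial
Nc1ccc(C(=O)O)cc1,commercial
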