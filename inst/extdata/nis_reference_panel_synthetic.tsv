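name	type	photolabile	membrane_bound
petrobactin_synthetase_like	petrobactin	TRUE	FALSE
vibrioferrin_synthetase_like	vibrioferrin	TRUE	FALSE
rhizoferrin_synthetase_like	rhizoferrin	TRUE	FALSE
aerobactin_synthetase_like	aerobactin	FALSE	FALSE
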