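population	treatment	replicate	pool_size
AS	AS	NA	140
AC	AC	NA	140
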