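# negation trigger phrases (one per line, natural form; normalized and
# stemmed at load time)
no
not
denies
denied
without
absent
negative for
no evidence of
free of
ruled out
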