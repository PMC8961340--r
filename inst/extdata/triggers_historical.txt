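# historical / past-temporality trigger phrases
history of
past medical history
previously
prior
years ago
remote
resolved
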