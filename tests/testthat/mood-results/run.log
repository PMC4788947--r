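14:45:40 mood frobnicate (seed 1, config f6405257)
14:51:04 mood frobnicate (seed 1, config f6405257)
14:59:16 mood frobnicate (seed 1, config f6405257)
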