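date,percent
2020-04-23,87.3
2020-04-27,79.2
2020-05-04,41.1
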