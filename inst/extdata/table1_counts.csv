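lens,method,cows_tested,n_success,n_fail
without,picture3,237,165,72
without,picture10,202,183,19
without,video,203,181,22
with,picture3,72,47,25
with,picture10,88,81,7
with,video,62,61,1
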