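drug,reason
drug003,target redundancy
drug011,no current clinical availability
drug027,established clinical futility
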