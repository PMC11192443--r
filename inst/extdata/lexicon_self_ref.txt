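i think
i believe
i guess
i feel
i felt
i thought
i assume
i suppose
in my opinion
i'm not sure
i am not sure
if i recall
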