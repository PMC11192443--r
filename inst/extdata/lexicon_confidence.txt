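it appears to be
appears to be
it appears
it seems to be
seems to be
it seems like
seems like
it seems
it looks like
looks like
it sounds like
sounds like
probably
maybe
perhaps
possibly
i'm pretty sure
i am pretty sure
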