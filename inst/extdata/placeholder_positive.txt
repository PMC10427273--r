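# Open placeholder lexicon: positive-emotion patterns (20 entries).
# One pattern per line; a trailing * matches any stem with that prefix.
# This is NOT a validated sentiment dictionary; it exists so the pipeline
# and tests run without proprietary word lists.
love*
happi*
joy*
sweet*
smile*
wonder*
beauti*
ador*
delight*
bless*
hope*
warm*
friend*
laugh*
peace*
charm*
glad
good
nice
brave
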