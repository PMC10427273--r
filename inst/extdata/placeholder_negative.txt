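# Open placeholder lexicon: negative-emotion patterns (24 entries).
# One pattern per line; a trailing * matches any stem with that prefix.
# This is NOT a validated sentiment dictionary; it exists so the pipeline
# and tests run without proprietary word lists.
hate*
sad*
hurt*
pain*
lonel*
fear*
evil*
kill*
death*
tear*
broke*
miser*
worri*
griev*
cry
cri
angri
anger
mad
die
dead
ugli
wicked
grief
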