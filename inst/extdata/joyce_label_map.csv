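label,category
sensation,S
irritation,E
despair,E
contempt,E
anger,E
tiredness,E
anxiety,E
reassurance,E
fear,E
thought,T
thought begins,T
thought progress,T
thought ends,T
recollection,T
conjecture,T
wish,T
plan,T
image,I
unfolding image,I
fantasy,I
fantasy developing,I
fantasy ends,I
visual image,I
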