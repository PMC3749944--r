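>strand1 binary template
AABB
>strand2 binary template
ABAB
>strand3 binary template
BBBA
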