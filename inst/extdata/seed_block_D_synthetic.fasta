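>seed_D_01 synthetic consensus-anchored
WFLHQDGS
>seed_D_02 synthetic consensus-anchored
WFLHQDGS
>seed_D_03 synthetic consensus-anchored
WFLHQDGS
>seed_D_04 synthetic consensus-anchored
WFLHQDGS
>seed_D_05 synthetic consensus-anchored
WFLHQDGS
>seed_D_06 synthetic consensus-anchored
WFLHQEGS
>seed_D_07 synthetic consensus-anchored
WYLHQDGS
>seed_D_08 synthetic consensus-anchored
WFLHQDGT
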