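>seed_A_01 synthetic consensus-anchored
CLSPGDRVIT
>seed_A_02 synthetic consensus-anchored
CLSPGDRVIT
>seed_A_03 synthetic consensus-anchored
CLAPGDRVIT
>seed_A_04 synthetic consensus-anchored
CLSPGDKVIT
>seed_A_05 synthetic consensus-anchored
SLSPGDRVIT
>seed_A_06 synthetic consensus-anchored
SLSPGDRVVT
>seed_A_07 synthetic consensus-anchored
ALSPGDRVIT
>seed_A_08 synthetic consensus-anchored
CLSPGERVIT
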