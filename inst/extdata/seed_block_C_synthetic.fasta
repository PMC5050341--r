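>seed_C_01 synthetic consensus-anchored
SLAGLIDADG
>seed_C_02 synthetic consensus-anchored
SLAGLIDADG
>seed_C_03 synthetic consensus-anchored
SLAGLIDADG
>seed_C_04 synthetic consensus-anchored
SLAGLIDADG
>seed_C_05 synthetic consensus-anchored
SLAGLIDADG
>seed_C_06 synthetic consensus-anchored
TLAGLIDADG
>seed_C_07 synthetic consensus-anchored
SLAGLVDADG
>seed_C_08 synthetic consensus-anchored
SLAGLIDSDG
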