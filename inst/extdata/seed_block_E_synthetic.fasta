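>seed_E_01 synthetic consensus-anchored
KLAGFIDADG
>seed_E_02 synthetic consensus-anchored
KLAGFIDADG
>seed_E_03 synthetic consensus-anchored
KLAGFIDADG
>seed_E_04 synthetic consensus-anchored
KLAGFIDADG
>seed_E_05 synthetic consensus-anchored
KLAGFIDADG
>seed_E_06 synthetic consensus-anchored
RLAGFIDADG
>seed_E_07 synthetic consensus-anchored
KLAGFVDADG
>seed_E_08 synthetic consensus-anchored
KLAGFIDGDG
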