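>seed_F_01 synthetic consensus-anchored
VFDCGLVRHY
>seed_F_02 synthetic consensus-anchored
VFDCGLVRHY
>seed_F_03 synthetic consensus-anchored
VFDCGLIRHY
>seed_F_04 synthetic consensus-anchored
VFDCGLVKHY
>seed_F_05 synthetic consensus-anchored
VFDVGLVRHY
>seed_F_06 synthetic consensus-anchored
VFDVGLVRHY
>seed_F_07 synthetic consensus-anchored
VFDVGLVRHE
>seed_F_08 synthetic consensus-anchored
VFDVALVRHY
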