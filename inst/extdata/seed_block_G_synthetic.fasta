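>seed_G_01 synthetic consensus-anchored
VKFLTHNC
>seed_G_02 synthetic consensus-anchored
VKFLTHNC
>seed_G_03 synthetic consensus-anchored
VKFLTHNC
>seed_G_04 synthetic consensus-anchored
VKFLTHNS
>seed_G_05 synthetic consensus-anchored
VKFLTGNC
>seed_G_06 synthetic consensus-anchored
VKFLTGNT
>seed_G_07 synthetic consensus-anchored
VKFLTKNC
>seed_G_08 synthetic consensus-anchored
VKFLTSQC
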