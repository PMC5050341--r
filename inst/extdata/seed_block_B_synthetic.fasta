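>seed_B_01 synthetic consensus-anchored
GRIYDLTVEGNGHT
>seed_B_02 synthetic consensus-anchored
GRIYDLTVEGNGHT
>seed_B_03 synthetic consensus-anchored
GRIYDLTVEGNWHT
>seed_B_04 synthetic consensus-anchored
GRIYDLTVEGNWHT
>seed_B_05 synthetic consensus-anchored
GRIYDLSVEGNWHT
>seed_B_06 synthetic consensus-anchored
GKIYDLTVEGNWHT
>seed_B_07 synthetic consensus-anchored
GRIYELTVEGNGHT
>seed_B_08 synthetic consensus-anchored
GRIYDLTVDGNGHT
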