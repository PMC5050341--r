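>seed_H_01 synthetic consensus-anchored
IRESLPYH
>seed_H_02 synthetic consensus-anchored
IRESLPYH
>seed_H_03 synthetic consensus-anchored
IRESLPYH
>seed_H_04 synthetic consensus-anchored
IRESLPYH
>seed_H_05 synthetic consensus-anchored
IRESLPYH
>seed_H_06 synthetic consensus-anchored
IKESLPYH
>seed_H_07 synthetic consensus-anchored
IRESLAYH
>seed_H_08 synthetic consensus-anchored
IRESLPYN
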