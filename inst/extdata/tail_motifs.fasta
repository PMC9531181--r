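>Ref11
GLGARSAGITH
>GA11
AGAGGAAGAGG
>GS11
SGSGGSSGSGG
>SUMO11
AKPSTEDLGDK
>polyG11
GGGGGGGGGGG
>polyS11
SSSSSSSSSSS
>ssrA
AANDENYALAA
>ssrADD
AANDENYALDD
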