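xread
'MRP matrix'
26 20
MRP_Outgroup 00000000000000000000000000
Genus02_sp02 ??????????110100010???????
Genus04_sp01 ???????????????????0000000
Genus04_sp02 1110000000000?????????????
Genus05_sp01 1110000000????????????????
Genus05_sp02 ?????????????1000111110000
Genus05_sp03 1001111100100??????1101100
Genus06_sp01 ?????????????111100???????
Genus06_sp02 1100000000???110000???????
Genus07_sp03 ???????????????????1101110
Genus08_sp01 10010000011111110001101000
Genus08_sp03 ???????????????????1000000
Genus09_sp02 1001000001111?????????????
Genus10_sp02 1001100000???1000111101111
Genus10_sp03 1001111000????????????????
Genus11_sp02 0000000000???0000001101111
Genus12_sp01 1001111110????????????????
Genus12_sp02 1001110000????????????????
Genus13_sp01 ???????????????????1110000
Genus14_sp01 1001111110???111100???????
;
proc /;
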