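specimen,region,volume_fraction,surface_fraction
Male 1,prosencephalon,0.63,0.61
Male 1,mesencephalon,0.17,0.18
Male 1,rhombencephalon,0.19,0.20
Male 2,prosencephalon,0.63,0.59
Male 2,mesencephalon,0.16,0.20
Male 2,rhombencephalon,0.21,0.21
Male 3,prosencephalon,0.61,0.55
Male 3,mesencephalon,0.17,0.23
Male 3,rhombencephalon,0.23,0.23
Female 1,prosencephalon,0.67,0.63
Female 1,mesencephalon,0.15,0.18
Female 1,rhombencephalon,0.18,0.19
Female 2,prosencephalon,0.65,0.62
Female 2,mesencephalon,0.17,0.18
Female 2,rhombencephalon,0.19,0.20
Female 3,prosencephalon,0.63,0.60
Female 3,mesencephalon,0.17,0.19
Female 3,rhombencephalon,0.20,0.21
Juvenile male 1,prosencephalon,0.64,0.60
Juvenile male 1,mesencephalon,0.16,0.17
Juvenile male 1,rhombencephalon,0.20,0.23
Juvenile male 2,prosencephalon,0.64,0.57
Juvenile male 2,mesencephalon,0.16,0.18
Juvenile male 2,rhombencephalon,0.20,0.24
Juvenile female 1,prosencephalon,0.66,0.61
Juvenile female 1,mesencephalon,0.15,0.16
Juvenile female 1,rhombencephalon,0.19,0.23
Juvenile female 2,prosencephalon,0.63,0.53
Juvenile female 2,mesencephalon,0.16,0.20
Juvenile female 2,rhombencephalon,0.21,0.27
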