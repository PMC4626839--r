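specimen,total_volume_mm3,total_surface_mm2
Male 1,3741,1500
Male 2,3526,1485
Male 3,3919,1630
Female 1,3493,1408
Female 2,3418,1424
Female 3,3238,1350
Juvenile male 1,2785,1273
Juvenile male 2,3068,1278
Juvenile female 1,2919,1363
Juvenile female 2,2735,1305
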