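specimen,sex,age_class,region,volume_mm3,surface_mm2
Male 1,male,adult,prosencephalon,2363,922
Male 1,male,adult,mesencephalon,652,277
Male 1,male,adult,rhombencephalon,726,301
Male 2,male,adult,prosencephalon,2229,882
Male 2,male,adult,mesencephalon,563,296
Male 2,male,adult,rhombencephalon,734,306
Male 3,male,adult,prosencephalon,2375,890
Male 3,male,adult,mesencephalon,661,370
Male 3,male,adult,rhombencephalon,883,370
Female 1,female,adult,prosencephalon,2343,893
Female 1,female,adult,mesencephalon,511,248
Female 1,female,adult,rhombencephalon,638,267
Female 2,female,adult,prosencephalon,2204,882
Female 2,female,adult,mesencephalon,570,262
Female 2,female,adult,rhombencephalon,643,280
Female 3,female,adult,prosencephalon,2026,808
Female 3,female,adult,mesencephalon,553,256
Female 3,female,adult,rhombencephalon,660,285
Juvenile male 1,male,juvenile,prosencephalon,1784,758
Juvenile male 1,male,juvenile,mesencephalon,443,222
Juvenile male 1,male,juvenile,rhombencephalon,558,293
Juvenile male 2,male,juvenile,prosencephalon,1964,734
Juvenile male 2,male,juvenile,mesencephalon,492,235
Juvenile male 2,male,juvenile,rhombencephalon,612,309
Juvenile female 1,female,juvenile,prosencephalon,1913,829
Juvenile female 1,female,juvenile,mesencephalon,437,222
Juvenile female 1,female,juvenile,rhombencephalon,569,312
Juvenile female 2,female,juvenile,prosencephalon,1731,692
Juvenile female 2,female,juvenile,mesencephalon,425,262
Juvenile female 2,female,juvenile,rhombencephalon,579,351
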