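muscle,plane,region,group,angle_deg
gluteus_maximus_caudal,frontal,middle,pooled,62.46
gluteus_maximus_caudal,frontal,middle,adult,65.2
gluteus_maximus_caudal,frontal,middle,juvenile,60.62
gluteus_maximus_caudal,frontal,dorsal,pooled,66.33
gluteus_maximus_caudal,frontal,dorsal,adult,68.72
gluteus_maximus_caudal,frontal,dorsal,juvenile,64.38
gluteus_maximus_cranial,frontal,middle,pooled,50.72
gluteus_maximus_cranial,frontal,middle,adult,52.52
gluteus_maximus_cranial,frontal,middle,juvenile,49.4
gluteus_maximus_cranial,frontal,dorsal,pooled,52.62
gluteus_maximus_cranial,frontal,dorsal,adult,51.95
gluteus_maximus_cranial,frontal,dorsal,juvenile,53.43
iliotibial_band,frontal,middle,pooled,6.48
iliotibial_band,frontal,dorsal,pooled,8.53
tensor_fasciae_latae,frontal,mean,pooled,19.85
tensor_fasciae_latae,frontal,mean,adult,20.14
tensor_fasciae_latae,frontal,mean,juvenile,19.35
gluteus_minimus,frontal,ventral,pooled,32.99
gluteus_minimus,frontal,ventral,adult,34.49
gluteus_minimus,frontal,ventral,juvenile,31.76
gluteus_minimus,frontal,middle,pooled,43.36
gluteus_minimus,frontal,middle,adult,44.17
gluteus_minimus,frontal,middle,juvenile,42.42
gluteus_medius,frontal,ventral,pooled,22.55
gluteus_medius,frontal,ventral,adult,26.44
gluteus_medius,frontal,ventral,juvenile,19.57
gluteus_medius,frontal,middle,pooled,33.56
gluteus_medius,frontal,middle,adult,37.01
gluteus_medius,frontal,middle,juvenile,30.29
gluteus_medius,frontal,dorsal,pooled,38.08
gluteus_medius,frontal,dorsal,adult,39.21
gluteus_medius,frontal,dorsal,juvenile,34.68
vastus_lateralis,frontal,ventral,pooled,-3.9
vastus_lateralis,frontal,ventral,adult,-3.9
vastus_lateralis,frontal,middle,pooled,-6.35
vastus_lateralis,frontal,middle,adult,-5.46
vastus_lateralis,frontal,middle,juvenile,-7.21
vastus_lateralis,frontal,dorsal,pooled,-8.24
vastus_lateralis,frontal,dorsal,adult,-8.39
vastus_lateralis,frontal,dorsal,juvenile,-8.08
piriformis,frontal,middle,pooled,48.64
piriformis,frontal,middle,adult,47.12
piriformis,frontal,middle,juvenile,49.65
piriformis,frontal,dorsal,pooled,49.2
piriformis,frontal,dorsal,adult,48.18
piriformis,frontal,dorsal,juvenile,50.74
triceps_coxae,frontal,ventral,pooled,80.43
triceps_coxae,frontal,ventral,adult,84
triceps_coxae,frontal,ventral,juvenile,78.64
triceps_coxae,frontal,middle,pooled,82.29
triceps_coxae,frontal,middle,adult,84.19
triceps_coxae,frontal,middle,juvenile,79.19
obturator_externus,frontal,ventral,pooled,-77.9
obturator_externus,frontal,ventral,adult,-79.66
obturator_externus,frontal,ventral,juvenile,-78.51
obturator_externus,frontal,middle,pooled,-69.06
obturator_externus,frontal,middle,adult,-70.34
obturator_externus,frontal,middle,juvenile,-68.03
obturator_externus,frontal,dorsal,pooled,-65.4
obturator_externus,frontal,dorsal,adult,-67.3
obturator_externus,frontal,dorsal,juvenile,-62.21
quadratus_femoris,frontal,middle,pooled,82.21
quadratus_femoris,frontal,middle,adult,85.64
quadratus_femoris,frontal,middle,juvenile,76.74
quadratus_femoris,frontal,dorsal,pooled,82.72
quadratus_femoris,frontal,dorsal,adult,86.62
quadratus_femoris,frontal,dorsal,juvenile,80.12
gluteus_maximus,transverse,cranial,pooled,-8.56
gluteus_maximus,transverse,cranial,adult,-8.61
gluteus_maximus,transverse,cranial,juvenile,-8.49
gluteus_maximus,transverse,middle,pooled,-8.34
gluteus_maximus,transverse,middle,adult,-8.41
gluteus_maximus,transverse,middle,juvenile,-8.23
gluteus_maximus,transverse,caudal,pooled,-8.33
gluteus_maximus,transverse,caudal,adult,-8.79
gluteus_maximus,transverse,caudal,juvenile,-7.61
piriformis,transverse,cranial,pooled,22.38
piriformis,transverse,cranial,adult,22.4
piriformis,transverse,cranial,juvenile,22.33
piriformis,transverse,middle,pooled,22.37
piriformis,transverse,middle,adult,22.3
piriformis,transverse,middle,juvenile,22.49
piriformis,transverse,caudal,pooled,22.39
piriformis,transverse,caudal,adult,22.36
piriformis,transverse,caudal,juvenile,22.41
triceps_coxae,transverse,middle,pooled,26.95
triceps_coxae,transverse,middle,adult,27
triceps_coxae,transverse,middle,juvenile,26.91
triceps_coxae,transverse,caudal,pooled,25.16
triceps_coxae,transverse,caudal,adult,23.84
triceps_coxae,transverse,caudal,juvenile,26.91
obturator_externus,transverse,middle,pooled,32.64
obturator_externus,transverse,middle,adult,30.19
obturator_externus,transverse,middle,juvenile,35.08
obturator_externus,transverse,caudal,pooled,31.04
obturator_externus,transverse,caudal,adult,29.16
obturator_externus,transverse,caudal,juvenile,34.42
quadratus_femoris,transverse,middle,pooled,-8.09
quadratus_femoris,transverse,middle,adult,-7
quadratus_femoris,transverse,middle,juvenile,-10.56
quadratus_femoris,transverse,caudal,pooled,-4.86
quadratus_femoris,transverse,caudal,adult,-4.77
quadratus_femoris,transverse,caudal,juvenile,-5.12
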