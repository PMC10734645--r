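source,muscle,pcsa_cm2,suspected_typo,corrected_cm2
brand,gluteus_maximus,46.04,FALSE,NA
brand,tensor_fasciae_latae,5.23,FALSE,NA
brand,gluteus_minimus,25.6,FALSE,NA
brand,gluteus_medius,47.8,FALSE,NA
brand,vastus_lateralis,40.445,FALSE,NA
brand,piriformis,14.85,FALSE,NA
brand,triceps_coxae,4.63,FALSE,NA
brand,obturator_externus,3795,TRUE,3.795
klein_horsmann,gluteus_maximus,71.1,FALSE,NA
klein_horsmann,tensor_fasciae_latae,8.8,FALSE,NA
klein_horsmann,gluteus_minimus,25.5,FALSE,NA
klein_horsmann,gluteus_medius,98.7,FALSE,NA
klein_horsmann,vastus_lateralis,34.85,FALSE,NA
klein_horsmann,piriformis,8.1,FALSE,NA
klein_horsmann,triceps_coxae,33.6,FALSE,NA
klein_horsmann,obturator_externus,24.6,FALSE,NA
klein_horsmann,quadratus_femoris,14.6,FALSE,NA
lube,gluteus_maximus,43,FALSE,NA
lube,tensor_fasciae_latae,5.9,FALSE,NA
lube,gluteus_minimus,16.2,FALSE,NA
lube,gluteus_medius,34.6,FALSE,NA
lube,vastus_lateralis,42.6,FALSE,NA
lube,piriformis,11.2,FALSE,NA
lube,triceps_coxae,21.7,FALSE,NA
lube,obturator_externus,8.2,FALSE,NA
lube,quadratus_femoris,4.6,FALSE,NA
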