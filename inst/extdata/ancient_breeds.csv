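breed,body_mass_g,brain_volume_ml
Greenland_sled_dog,31000,64.97
basenji,10000,54.88
akita_inu,44800,106.79
Saluki,22500,87.65
Siberian_husky,22954,90.33
Afghan_hound,22800,97.24
Samoyed,22250,90.39
Alaskan_Malamute,36900,113.94
Chinese_shar_pei,16900,83.96
chow_chow,25667,74.52
greyhound,31842,103.13
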