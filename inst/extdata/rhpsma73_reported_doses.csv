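# Published cohort-mean organ absorbed doses (mGy/MBq) of the
# first-in-humans F-18 rhPSMA-7.3 dosimetry study, reference adult
# phantom, 3.5-h voiding interval; SD over the 6 subjects.
organ,dose_mgy_per_mbq,sd_mgy_per_mbq
adrenals,0.184,0.053
kidneys,0.172,0.030
submandibular_glands,0.148,0.043
parotid_glands,0.114,0.025
spleen,0.083,0.024
lacrimal_glands,0.080,0.038
sublingual_glands,0.065,0.036
liver,0.062,0.006
pancreas,0.028,0.005
heart_wall,0.020,0.003
gallbladder_wall,0.017,0.001
urinary_bladder_wall,0.012,0.003
stomach_wall,0.012,0.001
small_intestine,0.012,0.003
osteogenic_cells,0.012,0.002
uterus,0.011,0.008
thymus,0.010,0.001
uli_wall,0.010,0.001
lungs,0.010,0.001
red_marrow,0.010,0.002
thyroid,0.010,0.002
lli_wall,0.007,0.002
muscle,0.006,0.001
testes,0.005,0.003
ovaries,0.005,0.001
breasts,0.004,0.002
skin,0.002,0.000
brain,0.002,0.000
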