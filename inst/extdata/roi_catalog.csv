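roi_id,class,pib_loading
frontal_ba9_l,cortical,0.9
frontal_ba9_r,cortical,0.9
frontal_ba10_l,cortical,0.9
frontal_ba10_r,cortical,0.9
cingulate_ant_ba24_l,cortical,0.9
cingulate_ant_ba24_r,cortical,0.9
cingulate_post_ba23_l,cortical,0.9
cingulate_post_ba23_r,cortical,0.9
parietal_ba7_l,cortical,0.9
parietal_ba7_r,cortical,0.9
parietal_ba40_l,cortical,0.9
parietal_ba40_r,cortical,0.9
temporal_ba21_l,cortical,0.9
temporal_ba21_r,cortical,0.9
temporal_ba38_l,cortical,0.9
temporal_ba38_r,cortical,0.9
occipital_ba17_l,cortical,0.9
occipital_ba17_r,cortical,0.9
occipital_ba19_l,cortical,0.9
occipital_ba19_r,cortical,0.9
caudate_l,striatal,1.0
caudate_r,striatal,1.0
putamen_l,striatal,1.0
putamen_r,striatal,1.0
thalamus_l,other_subcortical,0.5
thalamus_r,other_subcortical,0.5
hippocampus_l,other_subcortical,0.5
hippocampus_r,other_subcortical,0.5
amygdala_l,other_subcortical,0.5
amygdala_r,other_subcortical,0.5
cerebellum_sup,reference,0.0
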