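tissue,water,gelatin,lard,hydroxyapatite,sds
skin,75.0,25.0,0,0,0
muscle,74.78,19.97,5.0,0,0.25
adipose,0,0,100,0,0
spongiosa,26.61,11.83,47.43,12.81,1.32
ha_bone_45,55.0,0,0,45.0,0
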