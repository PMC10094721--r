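frame_id,d_OC14_react,dE_addition,chirality,geometry,dE_rotation,dE_reorganisation,dE_retro_abstraction
8721,3.2,3.0,S,Antarafacial,6.6,10.2,33.3
10106,3.2,4.3,S,Antarafacial,5.8,NA,NA
18168,3.1,3.1,S,Antarafacial,5.9,13.1,20.6
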