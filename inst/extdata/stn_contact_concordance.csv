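id,traj,stim_channels,erna_present,final_cathode
P01,1,0-1,Yes,1
P02,2,1-2,Yes,1
P03,1,0-1,No,2
P04,1,0-1,No,2
P05,1,0-1,Yes,0
P06,1,1-2,Yes,2
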