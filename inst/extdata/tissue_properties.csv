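label_id,name,sigma_S_per_m,eps_r,frequency_Hz
1,dura,0.367,1e6,40
2,csf_shell,1.79,109,40
3,gray_matter,0.276,4.07e7,40
4,white_matter,0.126,2.76e7,40
5,ventricular_csf,1.79,109,40
6,hippocampus,0.276,4.07e7,40
7,svz_shell,0.276,4.07e7,40
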