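cluster,n_current,n_subject,n_candidate,published_new_sites
1,2,228,5,0
2,0,2,0,0
3,0,2131,33,4
4,0,1577,20,3
5,21,20935,247,9
6,1,3336,32,4
7,1,187,4,0
8,12,2701,71,0
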