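cluster,n_current,n_subject,n_candidate,published_new_sites
1,9,2587,60,0
2,0,505,19,1
3,16,14888,131,6
4,0,34,0,0
5,1,187,4,0
6,3,303,7,0
7,0,2246,25,4
8,3,6780,136,8
9,5,3567,30,1
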