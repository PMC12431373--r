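fold,features,phi1,phi2,phi3,phi4
1,30;33;37,290,10,2,1
2,16;30;33,273,10,2,1
3,27;33;35;37,105,10,2,1
4,16;25;33,156,9,2,1
5,6;7;8;20;27,228,10,2,1
6,12;33;35,252,10,2,1
7,16;37,136,10,2,1
8,25;30;37,178,10,2,1
9,7;27;30;32,290,10,2,1
10,8;16,290,9,2,1
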