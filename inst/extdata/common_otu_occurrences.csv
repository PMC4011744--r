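otu_id,n_serrata,n_glauca,guild
757,106,56,other
167,40,31,EcM
115,36,20,other
329,31,16,other
1845,27,20,other
387,29,16,other
193,26,16,EcM
199,18,20,other
203,19,18,other
205,12,18,EcM
331,19,9,other
121,17,9,other
1089,25,0,EcM
211,11,12,EcM
169,14,5,EcM
823,14,5,other
867,17,2,other
425,7,11,EcM
185,15,1,EcM
375,9,7,other
411,7,7,other
527,4,10,other
207,11,1,other
393,5,7,other
517,10,2,EcM
1135,5,7,EcM
157,10,1,other
349,8,3,EcM
423,5,6,other
1157,8,3,EcM
113,3,7,EcM
153,6,4,EcM
195,8,2,other
623,3,7,other
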