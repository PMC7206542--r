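holder,position,row,name,buffer,is_buffer,concentration,volume
H1,1,A,lys_2mg,buf_tris,FALSE,2.0,50
H1,2,A,lys_5mg,buf_tris,FALSE,5.0,50
H1,3,A,buf_tris,,TRUE,,60
H1,4,B,bsa_3mg,buf_pbs,FALSE,3.0,50
H1,5,B,buf_pbs,,TRUE,,60
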