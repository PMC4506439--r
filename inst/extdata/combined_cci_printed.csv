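tissue,analyte,mean,sem,censor
nerve,IL1b,NA,NA,above_range
nerve,IL6,101.2,16.6,none
nerve,IL10,162.4,16.1,none
nerve,IL17A,35.2,2.4,none
nerve,IL18,71.1,2.6,none
nerve,TNF,77.6,12.1,none
nerve,IFNg,33.5,3.8,none
nerve,MCP1,440.2,34.1,none
drg,IL1b,98.9,8.8,none
drg,IL6,82.5,4.7,none
drg,IL10,251.1,18.0,none
drg,IL17A,89.0,6.6,none
drg,IL18,108.1,4.9,none
drg,TNF,28.7,1.3,none
drg,IFNg,46.7,4.9,none
drg,MCP1,149.0,7.6,none
spinal,IL1b,129.2,5.6,none
spinal,IL6,88.6,4.7,none
spinal,IL10,559.4,23.8,none
spinal,IL17A,356.8,21.4,none
spinal,IL18,116.2,5.5,none
spinal,TNF,66.6,1.9,none
spinal,IFNg,66.44,6.3,none
spinal,MCP1,135.6,3.5,none
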