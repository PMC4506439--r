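tissue,analyte,group,n,mean,sem,censor
nerve,IL1b,Sham,5,73.4,8.2,none
nerve,IL1b,PainDisability,5,NA,NA,above_range
nerve,IL1b,PainTransientDisability,4,NA,NA,above_range
nerve,IL1b,PainAlone,5,NA,NA,above_range
nerve,IL6,Sham,5,19.1,3.4,none
nerve,IL6,PainDisability,5,151.8,33.9,none
nerve,IL6,PainTransientDisability,4,61.4,13.1,none
nerve,IL6,PainAlone,5,82.5,20.2,none
nerve,IL10,Sham,5,189.2,36.2,none
nerve,IL10,PainDisability,5,135.6,19.4,none
nerve,IL10,PainTransientDisability,4,157.0,26.0,none
nerve,IL10,PainAlone,5,168.7,10.8,none
nerve,IL17A,Sham,5,55.7,1.6,none
nerve,IL17A,PainDisability,5,37.9,3.4,none
nerve,IL17A,PainTransientDisability,4,30.3,5.0,none
nerve,IL17A,PainAlone,5,36.4,4.4,none
nerve,IL18,Sham,5,77.8,7.1,none
nerve,IL18,PainDisability,5,73.2,6.1,none
nerve,IL18,PainTransientDisability,4,67.6,3.5,none
nerve,IL18,PainAlone,5,71.6,4.1,none
nerve,TNF,Sham,5,19.5,1.2,none
nerve,TNF,PainDisability,5,96.0,26.3,none
nerve,TNF,PainTransientDisability,4,61.2,8.3,none
nerve,TNF,PainAlone,5,72.4,23.4,none
nerve,IFNg,Sham,5,NA,NA,below_range
nerve,IFNg,PainDisability,5,35.9,9.1,none
nerve,IFNg,PainTransientDisability,4,34.0,0.6,none
nerve,IFNg,PainAlone,5,31.3,5.4,none
nerve,MCP1,Sham,5,151.2,42.7,none
nerve,MCP1,PainDisability,5,546.8,55.2,none
nerve,MCP1,PainTransientDisability,4,367.9,45.3,none
nerve,MCP1,PainAlone,5,391.5,51.5,none
drg,IL1b,Sham,5,65.3,10.4,none
drg,IL1b,PainDisability,5,102.1,16.6,none
drg,IL1b,PainTransientDisability,4,111.1,24.9,none
drg,IL1b,PainAlone,5,86.0,6.1,none
drg,IL6,Sham,5,35.7,6.8,none
drg,IL6,PainDisability,5,90.2,9.9,none
drg,IL6,PainTransientDisability,4,78.9,12.4,none
drg,IL6,PainAlone,5,77.5,2.2,none
drg,IL10,Sham,5,255.4,44.3,none
drg,IL10,PainDisability,5,217.2,21.0,none
drg,IL10,PainTransientDisability,4,310.6,34.2,none
drg,IL10,PainAlone,5,237.4,31.6,none
drg,IL17A,Sham,5,98.6,17.0,none
drg,IL17A,PainDisability,5,77.3,5.0,none
drg,IL17A,PainTransientDisability,4,106.7,18.1,none
drg,IL17A,PainAlone,5,86.5,10.6,none
drg,IL18,Sham,5,117.6,13.6,none
drg,IL18,PainDisability,5,98.7,6.9,none
drg,IL18,PainTransientDisability,4,123.5,9.7,none
drg,IL18,PainAlone,5,105.1,7.5,none
drg,TNF,Sham,5,30.0,3.2,none
drg,TNF,PainDisability,5,27.4,2.2,none
drg,TNF,PainTransientDisability,4,30.9,2.8,none
drg,TNF,PainAlone,5,28.3,2.4,none
drg,IFNg,Sham,5,47.1,10.8,none
drg,IFNg,PainDisability,5,42.2,6.0,none
drg,IFNg,PainTransientDisability,4,56.7,13.6,none
drg,IFNg,PainAlone,5,43.1,5.1,none
drg,MCP1,Sham,5,83.1,4.0,none
drg,MCP1,PainDisability,5,152.1,21.9,none
drg,MCP1,PainTransientDisability,4,136.8,7.8,none
drg,MCP1,PainAlone,5,155.4,3.8,none
spinal,IL1b,Sham,5,88.3,5.8,none
spinal,IL1b,PainDisability,5,143.6,9.3,none
spinal,IL1b,PainTransientDisability,4,116.8,6.4,none
spinal,IL1b,PainAlone,5,124.6,10.4,none
spinal,IL6,Sham,5,58.8,12.1,none
spinal,IL6,PainDisability,5,95.5,7.1,none
spinal,IL6,PainTransientDisability,4,92.3,9.8,none
spinal,IL6,PainAlone,5,78.9,8.3,none
spinal,IL10,Sham,5,467.6,54.3,none
spinal,IL10,PainDisability,5,573.6,19.8,none
spinal,IL10,PainTransientDisability,4,579.1,61.4,none
spinal,IL10,PainAlone,5,529.5,50.3,none
spinal,IL17A,Sham,5,277.5,33.8,none
spinal,IL17A,PainDisability,5,409.7,32.9,none
spinal,IL17A,PainTransientDisability,4,351.0,22.8,none
spinal,IL17A,PainAlone,5,308.6,42.7,none
spinal,IL18,Sham,5,104.0,11.6,none
spinal,IL18,PainDisability,5,112.2,6.4,none
spinal,IL18,PainTransientDisability,4,127.8,14.5,none
spinal,IL18,PainAlone,5,110.9,9.3,none
spinal,TNF,Sham,5,59.8,2.9,none
spinal,TNF,PainDisability,5,62.1,1.6,none
spinal,TNF,PainTransientDisability,4,70.2,4.3,none
spinal,TNF,PainAlone,5,66.4,3.7,none
spinal,IFNg,Sham,5,60.0,11.2,none
spinal,IFNg,PainDisability,5,53.4,9.0,none
spinal,IFNg,PainTransientDisability,4,65.3,15.3,none
spinal,IFNg,PainAlone,5,76.0,9.0,none
spinal,MCP1,Sham,5,111.7,10.3,none
spinal,MCP1,PainDisability,5,138.4,4.5,none
spinal,MCP1,PainTransientDisability,4,135.9,6.2,none
spinal,MCP1,PainAlone,5,132.6,8.4,none
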