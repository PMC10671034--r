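group,n,mean,min,max,f_value,h2,gcv,cv
All,370,44.5,17.2,79.9,6.2,77.3,24.1,19.1
ER-I,43,44.6,18.9,74.9,3.7,63.3,21.7,24.7
ER-II,103,42.0,17.2,69.5,5.3,72.1,22.9,20.3
ER-III,71,49.3,30.2,70.3,5.9,75.9,19.7,16.2
ER-IV,80,46.9,19.8,79.9,9.3,83.3,13.6,16.3
ER-V,34,41.7,25.0,62.1,5.7,77.5,20.1,16.6
ER-VI,39,40.2,20.3,67.5,6.6,80.1,28.4,21.4
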