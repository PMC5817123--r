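table,model,k,aic
growth_size,asymptotic,3,244.7364
growth_size,power,3,244.5961
largest_size,1,2,54.0536
largest_size,2,2,51.5745
largest_size,3,2,46.2726
largest_size,4,2,52.7792
largest_size,5,3,48.1799
largest_size,6,4,48.8814
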