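label,count,pct
Wake,9973,11.8
N1/N2,26626,31.6
N3,29289,34.8
REM,16402,19.5
Artifact,1919,2.3
Total,84209,100.0
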