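# Approximate circular season bands on the x0/X scale (winter wraps past 1).
# Replace with a laboratory reference set of modern known-birth caprines.
season,lower,upper
winter,0.90,0.30
spring,0.30,0.55
summer,0.55,0.65
autumn,0.65,0.90
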