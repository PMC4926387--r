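excipient,concentration,tm_c
none,1 mg/mL,79.37
trehalose,5% w/v,80.4
sucrose,5% w/v,80.16
mannitol,4% w/v,80.06
sorbitol,4% w/v,80.3
tween20,0.4% w/v,80.5
tween80,0.4% w/v,80.1
glycine,2% w/v,81.6
arginine,2% w/v,71.6
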