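excipient,pose,e_binding,hotspot
trehalose,1,-13.8,1
trehalose,2,-12.3,1
sucrose,1,-16.9,1
sucrose,2,-13.9,1
arginine,1,-22.7,2
glycine,1,-27.3,2
glycine,2,-25.3,2
mannitol,1,-11.9,2
mannitol,2,-10.7,2
mannitol,3,-7.8,2
sorbitol,1,-9.4,2
sorbitol,2,-8.9,2
sorbitol,3,-8.5,2
tween20,1,-14.4,3
tween20,2,-15.6,3
tween80,1,-18.9,3
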