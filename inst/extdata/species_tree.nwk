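(((Os:0.6,(Pd:0.4,Ma:0.4):0.2)monocots:0.3,((Vv:0.5,(Tc:0.35,At:0.35):0.15):0.1,Cc:0.6)dicots:0.3)mesangiosperms:0.3,Amb:0.9)root;
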