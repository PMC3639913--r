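pair_step	energy
AU/AU	-0.9
AU/UA	-1.1
AU/GC	-2.2
AU/CG	-2.1
AU/GU	-0.6
AU/UG	-1.4
UA/AU	-1.3
UA/UA	-0.9
UA/GC	-2.4
UA/CG	-2.1
UA/GU	-1.0
UA/UG	-1.3
GC/AU	-2.1
GC/UA	-2.2
GC/GC	-3.3
GC/CG	-3.4
GC/GU	-1.4
GC/UG	-2.5
CG/AU	-2.1
CG/UA	-2.4
CG/GC	-2.4
CG/CG	-3.3
CG/GU	-2.1
CG/UG	-2.1
GU/AU	-0.8
GU/UA	-1.0
GU/GC	-1.7
GU/CG	-2.1
GU/GU	-0.5
GU/UG	-0.3
UG/AU	-0.6
UG/UA	-0.7
UG/GC	-1.5
UG/CG	-1.9
UG/GU	-0.3
UG/UG	-0.5
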